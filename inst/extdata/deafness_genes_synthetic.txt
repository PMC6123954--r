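GPR98
PAX2
TECTA
LRIG3
LAMA2
CDH23
DMD
DUOX2
RBPJ
USH2A
MYO6
COL11A1
NAV2
CPXM2
COL4A4
LRP2
MYO15A
MYH9
TSPEAR
ACAN
PCDH15
OTOG
WFS1
MECOM
NTN1
GJB2
TCOF1
COL11A2
CELSR1
SLC9A3R1
COL9A1
TJP2
ALMS1
JAG1
ATP2B2
SLC26A4
LRIG1
LOXHD1
CHRNA9
RDX
CHD7
NTF3
ELMOD3
SLC4A7
ATP8B1
NPC1
KARS
ERCC6
HOMER2
WBP2
MIR96
KCNQ1
KCNQ4
OTOF
TRIOBP
GRM7
SIK3
TNF
IGF1
MBP
PTEN
SPRY2
IRS2
MYO7A
MYO1A
GJB6
GJB3
COCH
EYA4
EYA1
SIX1
POU4F3
POU3F4
TMC1
TMIE
TMPRSS3
ESPN
DIAPH1
ACTG1
CCDC50
GRHL2
SLC17A8
CEACAM16
P2RX2
OSBPL2
TBC1D24
DMXL2
MCM2
REST
PTPRQ
LMX1A
MYH14
GSDME
STRC
OTOA
PJVK
ESRRB
HGF
ILDR1
MARVELD2
TPRN
GIPC3
LHFPL5
COL2A1
COL4A3
COL4A5
MYO3A
WHRN
USH1C
USH1G
CLRN1
CIB2
CLDN14
EPS8
SYNE4
SERPINB6
BSND
KCNE1
KCNJ10
SLC26A5
CRYM
DSPP
EDN3
EDNRB
MITF
PAX3
SOX10
SNAI2
SEMA3E
TIMM8A
SMPX
PRPS1
AIFM1
COL9A2
COL9A3
OTOGL
TNC
MSRB3
GRXCR1
GRXCR2
PNPT1
ADCY1
CABP2
CLIC5
FAM65B
EPS8L2
NARS2
METTL13
ROR1
PDE1C
S1PR2
CDC14A
GRAP
PLS1
TMEM132E
CLDN9
SPNS2
GAS2
KLHL18
MINAR2
GREB1L
SYNDEAF001
SYNDEAF002
SYNDEAF003
SYNDEAF004
SYNDEAF005
SYNDEAF006
SYNDEAF007
SYNDEAF008
SYNDEAF009
SYNDEAF010
SYNDEAF011
SYNDEAF012
SYNDEAF013
SYNDEAF014
SYNDEAF015
SYNDEAF016
SYNDEAF017
SYNDEAF018
SYNDEAF019
SYNDEAF020
SYNDEAF021
SYNDEAF022
SYNDEAF023
SYNDEAF024
SYNDEAF025
SYNDEAF026
SYNDEAF027
SYNDEAF028
SYNDEAF029
SYNDEAF030
SYNDEAF031
SYNDEAF032
SYNDEAF033
SYNDEAF034
SYNDEAF035
SYNDEAF036
SYNDEAF037
SYNDEAF038
SYNDEAF039
SYNDEAF040
SYNDEAF041
SYNDEAF042
SYNDEAF043
SYNDEAF044
SYNDEAF045
SYNDEAF046
SYNDEAF047
SYNDEAF048
SYNDEAF049
SYNDEAF050
SYNDEAF051
SYNDEAF052
SYNDEAF053
SYNDEAF054
SYNDEAF055
SYNDEAF056
SYNDEAF057
SYNDEAF058
SYNDEAF059
SYNDEAF060
SYNDEAF061
SYNDEAF062
SYNDEAF063
SYNDEAF064
SYNDEAF065
SYNDEAF066
SYNDEAF067
SYNDEAF068
SYNDEAF069
SYNDEAF070
SYNDEAF071
SYNDEAF072
SYNDEAF073
SYNDEAF074
SYNDEAF075
SYNDEAF076
SYNDEAF077
SYNDEAF078
SYNDEAF079
SYNDEAF080
SYNDEAF081
SYNDEAF082
SYNDEAF083
SYNDEAF084
SYNDEAF085
SYNDEAF086
SYNDEAF087
SYNDEAF088
SYNDEAF089
SYNDEAF090
SYNDEAF091
SYNDEAF092
SYNDEAF093
SYNDEAF094
SYNDEAF095
SYNDEAF096
SYNDEAF097
SYNDEAF098
SYNDEAF099
SYNDEAF100
SYNDEAF101
SYNDEAF102
SYNDEAF103
SYNDEAF104
SYNDEAF105
SYNDEAF106
SYNDEAF107
SYNDEAF108
SYNDEAF109
SYNDEAF110
SYNDEAF111
SYNDEAF112
SYNDEAF113
SYNDEAF114
SYNDEAF115
SYNDEAF116
SYNDEAF117
SYNDEAF118
SYNDEAF119
SYNDEAF120
SYNDEAF121
SYNDEAF122
SYNDEAF123
SYNDEAF124
SYNDEAF125
SYNDEAF126
SYNDEAF127
SYNDEAF128
SYNDEAF129
SYNDEAF130
SYNDEAF131
SYNDEAF132
SYNDEAF133
SYNDEAF134
SYNDEAF135
SYNDEAF136
SYNDEAF137
SYNDEAF138
SYNDEAF139
SYNDEAF140
SYNDEAF141
SYNDEAF142
SYNDEAF143
SYNDEAF144
SYNDEAF145
SYNDEAF146
SYNDEAF147
SYNDEAF148
SYNDEAF149
SYNDEAF150
SYNDEAF151
SYNDEAF152
SYNDEAF153
SYNDEAF154
SYNDEAF155
SYNDEAF156
SYNDEAF157
SYNDEAF158
SYNDEAF159
SYNDEAF160
SYNDEAF161
SYNDEAF162
SYNDEAF163
SYNDEAF164
SYNDEAF165
SYNDEAF166
SYNDEAF167
SYNDEAF168
SYNDEAF169
SYNDEAF170
SYNDEAF171
SYNDEAF172
SYNDEAF173
SYNDEAF174
SYNDEAF175
SYNDEAF176
SYNDEAF177
SYNDEAF178
SYNDEAF179
SYNDEAF180
SYNDEAF181
SYNDEAF182
SYNDEAF183
SYNDEAF184
SYNDEAF185
SYNDEAF186
SYNDEAF187
SYNDEAF188
SYNDEAF189
SYNDEAF190
SYNDEAF191
SYNDEAF192
SYNDEAF193
SYNDEAF194
SYNDEAF195
SYNDEAF196
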