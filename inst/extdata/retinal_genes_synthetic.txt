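USH2A
MYO7A
CDH23
PCDH15
CLRN1
USH1C
USH1G
CIB2
ABCA4
RHO
RPGR
RPE65
RP1
RP2
PRPH2
CRB1
CEP290
GUCY2D
CRX
NRL
NR2E3
PDE6A
PDE6B
CNGA1
CNGB1
EYS
CERKL
MERTK
LRAT
TULP1
IMPDH1
PRPF31
PRPF8
PRPF3
SNRNP200
RDH12
AIPL1
LCA5
RPGRIP1
SPATA7
CHM
OPA1
TIMP3
EFEMP1
BEST1
CACNA1F
NYX
GPR179
TRPM1
GRM6
CNGA3
CNGB3
GNAT2
PDE6C
PDE6H
KCNV2
RS1
CHX10
VCAN
FZD4
LRP5
NDP
TSPAN12
RB1
ABHD12
CLN3
SYNRET001
SYNRET002
SYNRET003
SYNRET004
SYNRET005
SYNRET006
SYNRET007
SYNRET008
SYNRET009
SYNRET010
SYNRET011
SYNRET012
SYNRET013
SYNRET014
SYNRET015
SYNRET016
SYNRET017
SYNRET018
SYNRET019
SYNRET020
SYNRET021
SYNRET022
SYNRET023
SYNRET024
SYNRET025
SYNRET026
SYNRET027
SYNRET028
SYNRET029
SYNRET030
SYNRET031
SYNRET032
SYNRET033
SYNRET034
SYNRET035
SYNRET036
SYNRET037
SYNRET038
SYNRET039
SYNRET040
SYNRET041
SYNRET042
SYNRET043
SYNRET044
SYNRET045
SYNRET046
SYNRET047
SYNRET048
SYNRET049
SYNRET050
SYNRET051
SYNRET052
SYNRET053
SYNRET054
SYNRET055
SYNRET056
SYNRET057
SYNRET058
SYNRET059
SYNRET060
SYNRET061
SYNRET062
SYNRET063
SYNRET064
SYNRET065
SYNRET066
SYNRET067
SYNRET068
SYNRET069
SYNRET070
SYNRET071
SYNRET072
SYNRET073
SYNRET074
SYNRET075
SYNRET076
SYNRET077
SYNRET078
SYNRET079
SYNRET080
SYNRET081
SYNRET082
SYNRET083
SYNRET084
SYNRET085
SYNRET086
SYNRET087
SYNRET088
SYNRET089
SYNRET090
SYNRET091
SYNRET092
SYNRET093
SYNRET094
SYNRET095
SYNRET096
SYNRET097
SYNRET098
SYNRET099
SYNRET100
SYNRET101
SYNRET102
SYNRET103
SYNRET104
SYNRET105
SYNRET106
SYNRET107
SYNRET108
SYNRET109
SYNRET110
SYNRET111
SYNRET112
SYNRET113
SYNRET114
SYNRET115
SYNRET116
SYNRET117
SYNRET118
SYNRET119
SYNRET120
SYNRET121
SYNRET122
SYNRET123
SYNRET124
SYNRET125
SYNRET126
SYNRET127
SYNRET128
SYNRET129
SYNRET130
SYNRET131
SYNRET132
SYNRET133
SYNRET134
SYNRET135
SYNRET136
SYNRET137
SYNRET138
SYNRET139
SYNRET140
SYNRET141
SYNRET142
SYNRET143
SYNRET144
SYNRET145
SYNRET146
SYNRET147
SYNRET148
SYNRET149
SYNRET150
SYNRET151
SYNRET152
SYNRET153
SYNRET154
SYNRET155
SYNRET156
SYNRET157
SYNRET158
SYNRET159
SYNRET160
SYNRET161
SYNRET162
SYNRET163
SYNRET164
SYNRET165
SYNRET166
SYNRET167
SYNRET168
SYNRET169
SYNRET170
SYNRET171
SYNRET172
SYNRET173
SYNRET174
SYNRET175
SYNRET176
SYNRET177
SYNRET178
SYNRET179
SYNRET180
SYNRET181
SYNRET182
SYNRET183
SYNRET184
SYNRET185
SYNRET186
SYNRET187
SYNRET188
SYNRET189
SYNRET190
SYNRET191
SYNRET192
SYNRET193
SYNRET194
SYNRET195
SYNRET196
SYNRET197
SYNRET198
SYNRET199
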