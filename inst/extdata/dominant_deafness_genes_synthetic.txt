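WFS1
MYO6
HOMER2
MYH9
MYH14
COCH
KCNQ4
GJB2
GJB6
TECTA
COL11A2
GSDME
POU4F3
SLC17A8
ACTG1
EYA4
TMC1
DIAPH1
CCDC50
MYO7A
MYO1A
GRHL2
TJP2
SIX1
CEACAM16
P2RX2
OSBPL2
TBC1D24
DMXL2
MCM2
REST
LMX1A
CRYM
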