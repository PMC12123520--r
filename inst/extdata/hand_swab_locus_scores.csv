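locus,M1,M2,M3,M4,M5,M6,F1,F2,F3,F4,F5,F6
D3S1358,0,0,0,0,0,0,0,0,0,0,0,0
D1S1656,0,1,0,0,0,0,0,0,0,0,0,0
D2S441,0.5,0,0,0,0.5,0,0,0,0,0,0.5,0
D10S1248,0,0,0,0,0.5,0,0.5,0,0,0,0,0
D13S317,0,0.5,0,0,0,0,0,0,0.5,0,0,0
Penta E,1,0,0,0,0,0,0,0,0,0,0,0
D16S539,1,0,0,0,0,0,0,0,0,0,0,0
D18S51,0,0,0.5,0,1,0,0.5,0,0,0,0,0
D2S1338,0,0,0,0,0.5,0,0,0,0,0,0,0
CSF1PO,0,0,1,0,0,0,0,0,0,0,0,0
Penta D,0,0,0,0,0,0,0,0,0,0,0,0
TH01,0.5,0,0,0,0,0,0,0,0,0,0,0
vWA,1,0,0,0,1,0,0,0,0,0,0,0
D21S11,0,0,1,0,0.5,0,0,0,0,0,0,0
D7S820,0,0,0.5,0,1,0,0,0,0,0,0,0
D5S818,1,0,0,0,0,0,0,0,0,0,0,0
TPOX,0.5,0,0,0,0.5,0,0,0,0,0,0,0
D8S1179,1,0,0,0,0,0,0,0,0,0,0,0
D12S391,0.5,0,0.5,0,0,0.5,0,0,0,0,1,0
D19S433,0,0,0,0,0,0,0,0,0,0,0,0
SE33,0,0,0,0,0,0,0,0,0,0,0,0
D22S1045,1,0,0,0,0,0,0,0,0,0,0,0
DYS391,0,0,0,0,0,0,-,-,-,-,-,-
FGA,0.5,0,0,0,0,0,0,0,0,0,0.5,0
DYS576,0,0,0,0,0,0,-,-,-,-,-,-
DYS570,1,0,0,0,0,0,-,-,-,-,-,-
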