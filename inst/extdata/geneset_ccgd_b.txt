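# CCGD rank-B genes appearing in the truncating-variant reference table
ZMYND11
DNAH17
GATA3
NEMF
BTBD7
ITGB1
KLHDC2
MTA2
ODF2
PCCA
PPFIA3
RASGRF1
CLMN
KIAA0947_ENST00000296564/ICE1
OSBPL1A
RAB11A
ARHGAP29
SLTM
THOC5
NBR1
PRDM5
NFYB
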