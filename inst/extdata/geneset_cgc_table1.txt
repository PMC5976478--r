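# Cancer Gene Census members detected in the in-house exome cohort
PIK3CA
TP53
PRKAR1A
POLD1
CIITA
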