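factor,CTT_PCA,GA,TE
EXT,0.96,0.98,0.98
EST,0.94,0.97,0.97
AGR,0.93,0.96,0.95
CSN,0.95,0.96,0.95
OPN,0.94,0.96,0.95
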