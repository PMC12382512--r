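factor,origin,CTT_PCA,GA,TE
EXT,0.91,0.88,0.86,0.85
EST,0.88,0.87,0.83,0.82
AGR,0.85,0.85,0.74,0.81
CSN,0.83,0.81,0.76,0.76
OPN,0.81,0.76,0.71,0.73
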