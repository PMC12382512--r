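cluster,AGR,CSN,EST,EXT,OPN
0,0,0,0,9,0
1,0,0,10,0,0
2,0,10,0,0,0
3,0,0,0,0,9
4,10,0,0,1,1
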