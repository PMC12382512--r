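item_id,text,cluster,subscale,silhouette,distance
AGR10,I make people feel at ease.,4,AGR,0.50,0.40
AGR4,I sympathize with others' feelings.,4,AGR,0.46,0.41
AGR5,I am interested in other people's problems.,4,AGR,0.39,0.30
AGR6,I have a soft heart.,4,AGR,0.13,0.34
AGR8,I take time out for others.,4,AGR,0.52,0.44
AGR9,I feel others' emotions.,4,AGR,0.24,0.36
CSN1,I am always prepared.,2,CSN,0.46,0.36
CSN10,I am exacting in my work.,2,CSN,0.67,0.26
CSN2,I keep my belongings organized.,2,CSN,0.61,0.34
CSN4,I keep things tidy.,2,CSN,0.68,0.50
CSN5,I get chores done right away.,2,CSN,0.60,0.42
CSN8,I take responsibility for my duties.,2,CSN,0.58,0.57
EST1,I get stressed out easily.,1,EST,0.70,0.36
EST4,I often feel blue.,1,EST,0.65,0.35
EST5,I am easily disturbed.,1,EST,0.64,0.32
EST6,I get upset easily.,1,EST,0.67,0.31
EST7,I change my mood a lot.,1,EST,0.73,0.44
EST8,I have frequent mood swings.,1,EST,0.71,0.44
EXT1,I am the life of the party.,0,EXT,0.61,0.35
EXT10,I am talkative around strangers.,0,EXT,0.51,0.35
EXT4,I take the lead.,0,EXT,0.35,0.26
EXT6,I have a lot to say.,0,EXT,0.06,0.49
EXT7,I talk to a lot of different people at parties.,0,EXT,0.58,0.45
EXT9,I don't mind being the center of attention.,0,EXT,0.52,0.50
OPN1,I have a rich vocabulary.,3,OPN,0.48,0.71
OPN2,I understand abstract ideas easily.,3,OPN,0.58,0.69
OPN3,I have a vivid imagination.,3,OPN,0.51,0.49
OPN4,I am interested in abstract ideas.,3,OPN,0.31,0.72
OPN6,I have a good imagination.,3,OPN,0.57,0.67
OPN7,I am quick to understand things.,3,OPN,0.13,0.60
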