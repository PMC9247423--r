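age_group,weight
50-54,0.2168861348
55-59,0.1982958947
60-64,0.1549186677
65-69,0.1208365608
70-74,0.1006971340
75-79,0.0867544539
80-84,0.0666150271
85-89,0.0371804802
90-94,0.0139426801
95+,0.0038729667
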