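"time","n_risk"
0,200
3,58
6,26
9,10
12,5
15,0
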