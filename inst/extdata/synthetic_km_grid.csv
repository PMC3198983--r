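"time","survival"
0,1
0.75,0.850336603295931
1.5,0.755679345524167
2.25,0.633687484616188
3,0.550451018259186
3.75,0.530942696730843
4.5,0.482174218619084
5.25,0.467106274287237
6,0.450423907348408
6.75,0.415775914475453
7.5,0.415775914475453
8.25,0.389789919820737
9,0.327096436213206
9.75,0.327096436213206
10.5,0.327096436213206
11.25,0.327096436213206
12,0.233640311580862
12.75,0.233640311580862
13.5,0
14.25,0
15,0
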