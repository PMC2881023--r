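resistant_score	-2	-1	0	1	2
-2	5	1	1	0	0
-1	14	18	7	0	0
0	26	177	8153	94	17
1	0	0	30	12	26
2	0	0	2	2	20
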