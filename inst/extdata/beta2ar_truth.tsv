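index	h1	h2
1	-1	1
2	1	1
3	1	-1
4	-1	1
5	-1	1
6	-1	1
7	-1	1
8	1	-1
9	-1	1
10	1	1
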