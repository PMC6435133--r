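1 r1 1 100 ~~~
1 r2 3 0111 ~~~~
2 r3 3 01 9 10 ~~~~
1 r4 1 001000 ~~~~~~
2 r5 3 1 6 00100 ~~~~~~
2 r6 1 00 5 00 ~~~~
3 r7 1 10 5 1 10 0 ~~~~
2 r8 1 10 5 111 ~~~~~
3 r9 1 0 4 0 7 010 ~~~~~
2 r10 3 10 9 00 ~~~~
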