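label	level
3a	0
3b	0
1	1
2	2
5	3
Rl	4
Sll	5
7a	6
7b	6
4	7
lg	7
SMA	8
6	8
ld	8
35	9
36	9
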