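dim	birth	death	multiplicity
0	0	inf	8
0	0	1	286
1	1	2	16
1	1	3	19
1	1	4	5
1	1	5	3
1	1	6	2
1	1	7	1
2	2	3	4
2	3	4	11
2	4	5	12
2	5	6	4
2	6	7	5
2	7	8	1
2	8	9	1
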