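chr	group	n_blocks	mean_length_cm
1	entire	8	2.9
2	entire	8	5.9
3	entire	3	9.6
4	entire	2	7.9
5	entire	3	11
6	entire	4	8.2
7	entire	5	7.9
8	entire	4	14.4
9	entire	3	4.6
10	entire	8	5.4
11	entire	6	3.8
12	entire	2	3.3
1	SG1	7	4.5
2	SG1	3	8.1
3	SG1	6	2.1
4	SG1	5	8.1
5	SG1	0	0
6	SG1	6	6.9
7	SG1	3	11.2
8	SG1	3	2.4
9	SG1	1	0.8
10	SG1	3	13.4
11	SG1	1	2.9
12	SG1	1	3.8
1	SG2	1	3.2
2	SG2	0	0
3	SG2	2	2.4
4	SG2	1	1.4
5	SG2	1	6.5
6	SG2	2	2.3
7	SG2	1	2.2
8	SG2	1	8.1
9	SG2	0	0
10	SG2	1	6.9
11	SG2	0	0
12	SG2	1	3.8
1	AD	1	19.6
2	AD	4	5.1
3	AD	0	0
4	AD	2	13.9
5	AD	1	1.9
6	AD	2	2.3
7	AD	0	0
8	AD	0	0
9	AD	2	5.8
10	AD	1	1.1
11	AD	3	6.1
12	AD	0	0
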