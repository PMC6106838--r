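0	1	0.98
0	2	0.95
0	3	0.88
0	4	0.78
0	5	0.2
0	8	0.2
0	9	0.2
1	2	0.87
1	3	0.87
1	5	0.2
1	8	0.2
1	9	0.2
10	5	0.2
10	8	0.2
11	5	0.2
11	8	0.2
12	5	0.2
13	14	0.2
13	15	0.2
13	16	0.2
13	8	0.2
13	9	0.2
14	15	0.2
14	16	0.2
14	8	0.2
14	9	0.2
15	16	0.2
15	8	0.2
15	9	0.2
16	8	0.2
17	18	0.2
17	8	0.2
18	19	0.2
19	20	0.2
2	3	0.85
2	4	0.85
2	5	0.2
2	8	0.2
20	21	0.2
3	4	0.85
3	5	0.2
3	9	0.2
4	6	0.2
4	7	0.2
4	8	0.2
5	6	0.2
5	7	0.2
6	7	0.2
7	8	0.2
7	9	0.2
8	9	0.2
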