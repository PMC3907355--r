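family	n_members	most_distant_degree	population
1	16	5	ASI
2	7	2	ASI
3	25	3	CEU
4	10	3	CEU
5	4	1	CEU
6	5	1	CEU
7	5	1	CEU
8	7	12	CEU
9	10	11	CEU
10	4	6	CEU
11	17	2	CEU
12	4	1	CEU
13	4	1	CEU
14	5	1	CEU
15	4	2	CEU
16	15	4	CEU
17	10	3	CEU
18	7	2	CEU
19	7	2	CEU
20	8	3	CEU
21	9	2	CEU
22	15	3	CEU
23	4	1	CEU
24	4	5	CEU
25	4	1	CEU
26	4	1	CEU
27	4	1	CEU
28	6	2	MXL
29	25	5	MXL
30	9	1	MXL
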