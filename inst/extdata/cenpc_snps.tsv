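snp	name	change	polymorphism_type	position	coverage	variant_coverage	genomic_detected	in_duplication	reported_proportion	v_common	g_common	reported_p_common	v_variant	g_variant	reported_p_variant
1	G	C -> G	SNP (transversion)	106	16	13	Yes	No	0.81	5	3	1.95E-01	4	4	2.13E-02
2	G	A -> G	SNP (transition)	150	19	8	Yes	No	0.42	1	7	1.25E-03	2	6	1.08E-01
3	C	G -> C	SNP (transversion)	246	34	7	Yes	No	0.21	1	7	1.87E-01	2	6	6.93E-01
4	T	A -> T	SNP (transversion)	369	65	7	Yes	No	0.11	1	7	8.51E-01	2	6	6.14E-03
5	A	G -> A	SNP (transition)	371	68	19	No	No	0.28	1	7	6.21E-04	1	7	6.21E-04
6	C	T -> C	SNP (transition)	390	64	15	No	No	0.23	1	7	1.32E-02	1	7	1.32E-02
7	G	T -> G	SNP (transversion)	513	46	12	Yes	No	0.26	3	5	1.28E-01	4	4	1.64E-03
8	A	G -> A	SNP (transition)	518	45	10	Yes	No	0.22	2	6	7.34E-01	3	5	4.40E-02
9	T	G -> T	SNP (transversion)	731	54	8	Yes	No	0.15	2	6	1.14E-01	3	5	3.58E-04
10	C	A -> C	SNP (transversion)	1008	56	9	No	No	0.16	1	7	4.17E-01	1	7	4.17E-01
11	T	C -> T	SNP (transition)	1061	91	29	Yes	No	0.32	2	6	1.46E-01	3	5	2.81E-01
12	T	C -> T	SNP (transition)	1088	77	41	Yes	No	0.53	4	4	6.48E-01	3	5	6.37E-03
13	T	C -> T	SNP (transition)	1190	76	9	Yes	No	0.12	2	6	7.49E-03	3	5	1.10E-06
14	A	G -> A	SNP (transition)	1209	76	20	No	No	0.26	1	7	1.31E-03	1	7	1.31E-03
15	T	A -> T	SNP (transversion)	1251	62	10	Yes	No	0.16	2	6	1.41E-01	3	5	3.29E-04
16	G	A -> G	SNP (transition)	1255	62	55	Yes	No	0.89	6	2	1.19E-02	5	3	5.15E-06
17		-ATG	Deletion	1307	75	9	Yes	No	0.12	1	7	1.00E+00	2	6	7.38E-03
18	G	A -> G	SNP (transition)	1314	90	23	Yes	No	0.26	1	7	6.50E-04	2	6	9.03E-01
19	G	T -> G	SNP (transversion)	1347	103	13	Yes	No	0.13	2	6	2.88E-03	3	5	3.09E-08
20	A	T -> A	SNP (transversion)	1384	101	37	Yes	No	0.37	1	7	5.30E-10	2	6	1.09E-02
21	G	C -> G	SNP (transversion)	1424	80	9	No	No	0.11	1	7	8.66E-01	1	7	8.66E-01
22	A	C -> A	SNP (transversion)	1437	84	10	Yes	No	0.12	1	7	1.00E+00	2	6	5.12E-03
23	TT	AA -> TT	Substitution	1481	62	7	No	No	0.11	1	7	1.00E+00	1	7	1.00E+00
24	G	A -> G	SNP (transition)	1527	106	90	Yes	Yes	0.85						
25	C	T -> C	SNP (transition)	1540	139	86	Yes	Yes	0.62						
26	A	T -> A	SNP (transversion)	1584	253	235	Yes	Yes	0.93						
27	A	G -> A	SNP (transition)	1638	247	39	Yes	Yes	0.16						
28	C	A -> C	SNP (transversion)	1648	209	106	Yes	Yes	0.51						
29	A	C -> A	SNP (transversion)	1739	122	16	Yes	Yes	0.13						
30	T	C -> T	SNP (transition)	1751	132	32	Yes	Yes	0.24						
31	A	G -> A	SNP (transition)	1753	138	16	Yes	Yes	0.12						
32	A	C -> A	SNP (transversion)	1762	131	21	No	Yes	0.16						
33	T	A -> T	SNP (transversion)	1776	125	75	Yes	Yes	0.6						
34	C	G -> C	SNP (transversion)	1796	88	31	No	Yes	0.35						
35	G	C -> G	SNP (transversion)	1808	37	25	Yes	No	0.68	4	3	0.00E+00	4	4	8.90E-01
36	T	C -> T	SNP (transition)	1808	78	41	Yes	Yes	0.53						
37	T	C -> T	SNP (transition)	1814	78	27	Yes	Yes	0.35						
38	T	C -> T	SNP (transition)	1827	68	7	Yes	Yes	0.1						
39	A	T -> A	SNP (transversion)	1830	65	8	Yes	Yes	0.12						
40	A	G -> A	SNP (transition)	1839	62	23	Yes	Yes	0.37						
41	A	G -> A	SNP (transition)	1853	52	6	Yes	Yes	0.12						
42	C	A -> C	SNP (transversion)	1866	47	30	Yes	Yes	0.64						
43	A	C -> A	SNP (transversion)	1910	152	34	Yes	Yes	0.22						
44	A	G -> A	SNP (transition)	1917	158	103	Yes	Yes	0.65						
45	G	T -> G	SNP (transversion)	1922	165	110	Yes	Yes	0.67						
46	T	A -> T	SNP (transversion)	1938	170	41	Yes	Yes	0.24						
47	A	C -> A	SNP (transversion)	2039	196	37	Yes	Yes	0.19						
48	T	C -> T	SNP (transition)	2043	196	143	Yes	Yes	0.73						
49	G	T -> G	SNP (transversion)	2080	177	88	Yes	Yes	0.5						
50	C	A -> C	SNP (transversion)	2123	126	89	Yes	Yes	0.71						
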