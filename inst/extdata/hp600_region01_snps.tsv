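snp	name	change	polymorphism_type	position	coverage	variant_coverage	genomic_detected	in_duplication	reported_proportion	v_common	g_common	reported_p_common	v_variant	g_variant	reported_p_variant
1	C	G -> C	SNP (transversion)	12	443	101	Yes	No	0.23	1	7	2.32E-09	2	6	2.98E-01
2	-	-C	Deletion	78	515	28	Yes	No	0.05	1	7	1.13E-07	2	6	4.76E-32
3	T	C -> T	SNP (transition)	133	542	38	Yes	No	0.07	1	7	5.16E-05	2	6	1.62E-27
4	A	G -> A	SNP (transition)	153	577	33	Yes	No	0.06	1	7	9.76E-08	2	6	1.56E-34
5	TT	GG -> TT	Substitution	166	699	137	Yes	No	0.2	1	7	1.18E-07	2	6	8.85E-04
6	T	C -> T	SNP (transition)	263	569	55	No	No	0.1	1	7	4.23E-02	1	7	4.23E-02
7		(GAG)3 -> (GAG)2	Deletion (tandem repeat)	283	654	42	No	No	0.06	1	7	4.35E-07	1	7	4.35E-07
8	C	T -> C	SNP (transition)	429	849	83	No	No	0.1	1	7	1.68E-02	1	7	1.68E-02
9	A	G -> A	SNP (transition)	434	993	69	No	No	0.07	1	7	1.68E-08	1	7	1.68E-08
10	C	G -> C	SNP (transversion)	436	1035	275	Yes	No	0.27	2	6	2.51E-01	3	5	1.196E-13
11	T	G -> T	SNP (transversion)	463	936	56	No	No	0.06	1	7	5.11E-11	1	7	5.11E-11
12	A	C -> A	SNP (transversion)	519	679	57	No	No	0.08	1	7	9.10E-04	1	7	9.10E-04
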