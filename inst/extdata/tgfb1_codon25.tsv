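study_id	polymorphism	disease	n_case	n_control	case_aa	case_ab	case_bb	ctrl_aa	ctrl_ab	ctrl_bb	allele_common	allele_variant	hwe_case	hwe_control
Armendariz 2008 ALD	codon 25	ALD	7	30	7	0	0	11	13	6	Arg	Pro	/	0.552
Armendariz 2008 CHC	codon 25	CHC	13	30	13	0	0	11	13	6	Arg	Pro	/	0.552
Basturk 2008	codon 25	CHB	27	60	23	4	0	51	6	3	Arg	Pro	0.678	0.001
Dondeti 2017	codon 25	CHB	115	119	96	19	0	104	13	2	Arg	Pro	0.334	0.054
Fabricio-Silva 2015	codon 25	CHC	245	189	213	30	2	161	26	2	Arg	Pro	0.417	0.420
Falleti 2008	codon 25	Cirrhosis	187	140	156	31	0	127	13	0	Arg	Pro	0.216	0.565
Hosseini Razavi 2014	codon 25	CHB	220	220	193	23	4	197	21	2	Arg	Pro	0.003	0.105
Maria 2013	codon 25	CHC	38	50	34	4	0	46	4	0	Arg	Pro	0.732	0.768
Nomair 2021 Cirrhosis	codon 25	Cirrhosis	36	20	2	32	2	4	14	2	Arg	Pro	0.000	0.064
Nomair 2021 HCC	codon 25	HCC	34	20	10	24	0	4	14	2	Arg	Pro	0.001	0.064
Obada 2017	codon 25	CHC	150	100	127	22	1	84	15	1	Arg	Pro	0.965	0.721
Oliver 2005	codon 25	ALD	165	185	135	28	2	148	34	3	Arg	Pro	0.690	0.523
Paladino 2010	codon 25	AIH	178	189	154	15	9	156	32	1	Arg	Pro	0.000	0.638
Pereira 2008	codon 25	CHC	128	94	113	14	1	64	29	1	Arg	Pro	0.451	0.244
Romani 2011	codon 25	CHC	164	169	145	18	1	151	16	2	Arg	Pro	0.595	0.052
Sanchez-Parada 2013	codon 25	CHC	38	50	34	4	0	46	4	0	Arg	Pro	0.732	0.768
Vidigal 2002	codon 25	CHC	80	37	68	11	1	34	3	0	Arg	Pro	0.480	0.797
Yousefi 2019	codon 25	AIH	43	138	26	7	10	119	17	2	Arg	Pro	0.000	0.146
Zein 2004 Caucasian	codon 25	CHC	31	36	25	6	0	33	3	0	Arg	Pro	0.551	0.794
Zein 2004 Egyptian	codon 25	CHC	24	45	21	3	0	41	4	0	Arg	Pro	0.744	0.755
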