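study_id	polymorphism	disease	n_case	n_control	case_aa	case_ab	case_bb	ctrl_aa	ctrl_ab	ctrl_bb	allele_common	allele_variant	hwe_case	hwe_control
Bader El Din 2017	-509C/T	CHC	72	50	22	32	18	23	23	4	C	T	0.358	0.595
Brito 2020	-509C/T	CHC	97	300	17	49	31	90	154	56	C	T	0.754	0.488
Conde 2013	-509C/T	CHB	53	97	17	19	17	24	39	34	C	T	0.039	0.065
Dondeti 2017	-509C/T	CHB	115	119	11	85	19	35	75	9	C	T	0.000	0.000
Eskandari 2017	-509C/T	CHB	178	154	78	78	22	71	54	29	C	T	0.715	0.003
Falleti 2008	-509C/T	Cirrhosis	188	140	50	85	53	57	61	22	C	T	0.190	0.404
Ghani 2019 CHC	-509C/T	CHC	96	98	22	47	27	38	42	18	C	T	0.859	0.296
Ghani 2019 HCC	-509C/T	HCC	94	98	18	47	29	38	42	18	C	T	0.893	0.296
Hosseini Razavi 2014	-509C/T	CHB	220	220	50	116	54	65	97	58	C	T	0.416	0.082
Kikuchi 2007	-509C/T	PBC	65	71	21	32	12	27	31	13	C	T	0.975	0.441
Ma 2015 CHC	-509C/T	CHC	234	375	91	101	42	143	161	71	C	T	0.137	0.036
Ma 2015 HCC	-509C/T	HCC	159	375	50	67	42	143	161	71	C	T	0.051	0.036
Mohy 2014	-509C/T	Cirrhosis	40	40	9	21	10	33	4	3	C	T	0.749	0.001
Oliver 2005	-509C/T	ALD	165	185	64	78	23	79	85	21	C	T	0.921	0.795
Qi 2009 CHB	-509C/T	CHB	196	299	31	101	64	50	156	93	C	T	0.396	0.257
Qi 2009 HCC	-509C/T	HCC	379	299	89	198	92	50	156	93	C	T	0.382	0.257
Radwan 2012 Cirrhosis	-509C/T	Cirrhosis	152	160	34	74	44	62	68	30	C	T	0.785	0.147
Radwan 2012 HCC	-509C/T	HCC	128	160	24	64	40	62	68	30	C	T	0.857	0.147
Roy 2012	-509C/T	ALD	169	108	80	75	14	39	48	21	C	T	0.539	0.373
Shi 2012	-509C/T	HCC	72	117	24	40	8	55	53	9	C	T	0.152	0.438
Wang 2008	-509C/T	Cirrhosis	118	104	31	53	34	29	50	25	C	T	0.272	0.706
Xin 2012	-509C/T	HCC	347	881	82	177	88	212	432	237	C	T	0.703	0.583
Saxena 2014 CHB	-509C/T	CHB	61	153	8	37	16	44	94	15	C	T	0.067	0.001
Saxena 2014 Cirrhosis	-509C/T	Cirrhosis	60	153	8	48	4	44	94	15	C	T	0.000	0.001
Saxena 2014 HCC	-509C/T	HCC	59	153	9	39	11	44	94	15	C	T	0.013	0.001
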