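block	block_pos	block_size_bp	probeset	gene_name	avg_exp	avg_exp_male	avg_exp_female	wilcox_pval	mf_ratio	n_corr	n_neg	n_pos
1	chrZ:16135000-16142000	7000	ENSGALG00000014908	FST	342.26	341.96	342.64	1.00E+00	1	0	0	0
1	chrZ:16135000-16142000	7000	ENSGALG00000028026	NDUFS4	3515.57	4107.78	2772.6	7.50E-07	1.48	7	0	7
1	chrZ:16135000-16142000	7000	ENSGALG00000053142	NA	NA	NA	NA	NA	NA	0	0	0
1	chrZ:16135000-16142000	7000	est_01	NA	159.84	175.81	139.79	6.30E-02	1.26	6	0	6
1	chrZ:16135000-16142000	7000	est_02	NA	232.83	238.2	226.09	1.00E+00	1.05	0	0	0
2	chrZ:22394000-22400000	6000	est_03	NA	153.42	162.07	142.57	1.00E+00	1.14	2	0	2
2	chrZ:22394000-22400000	6000	est_04	NA	2818.28	2975.23	2621.37	1.30E-03	1.13	2	0	2
2	chrZ:22394000-22400000	6000	ENSGALG00000014819	JMY	633.88	694.36	558	5.20E-02	1.24	6	0	6
2	chrZ:22394000-22400000	6000	ENSGALG00000050556	NA	NA	NA	NA	NA	NA	0	0	0
2	chrZ:22394000-22400000	6000	ENSGALG00000004518	BHMT2	3902.54	4265.37	3447.35	1.70E-04	1.24	6	0	6
2	chrZ:22394000-22400000	6000	ENSGALG00000004491	DMGDH	761.17	818.52	689.21	4.90E-01	1.19	2	0	2
2	chrZ:22394000-22400000	6000	est_05	NA	38.39	37.1	39.93	1.00E+00	0.93	4	4	0
2	chrZ:22394000-22400000	6000	est_06	NA	212.49	241.69	175.84	3.10E-03	1.37	6	0	6
3	chrZ:27141000-27149000	8000	est_07	NA	101	104.55	96.61	1.00E+00	1.08	0	0	0
3	chrZ:27141000-27149000	8000	ENSGALG00000010187	SLC1A1	556.46	540.19	576.88	1.00E+00	0.94	0	0	0
3	chrZ:27141000-27149000	8000	est_08	NA	368.04	364.47	372.52	1.00E+00	0.98	0	0	0
3	chrZ:27141000-27149000	8000	est_09	NA	28.85	28.79	28.92	1.00E+00	1	0	0	0
3	chrZ:27141000-27149000	8000	ENSGALG00000053562	NA	NA	NA	NA	NA	NA	0	0	0
4	chrZ:27150000-27160000	10000	est_07	NA	101	104.55	96.61	1.00E+00	1.08	0	0	0
4	chrZ:27150000-27160000	10000	ENSGALG00000010187	SLC1A1	556.46	540.19	576.88	1.00E+00	0.94	0	0	0
4	chrZ:27150000-27160000	10000	est_08	NA	368.04	364.47	372.52	1.00E+00	0.98	0	0	0
4	chrZ:27150000-27160000	10000	est_09	NA	28.85	28.79	28.92	1.00E+00	1	0	0	0
4	chrZ:27150000-27160000	10000	ENSGALG00000053562	NA	NA	NA	NA	NA	NA	0	0	0
4	chrZ:27150000-27160000	10000	ENSGALG00000048068	NA	NA	NA	NA	NA	NA	0	0	0
5	chrZ:27236000-27245000	9000	ENSGALG00000053562	NA	NA	NA	NA	NA	NA	0	0	0
5	chrZ:27236000-27245000	9000	ENSGALG00000050012	NA	NA	NA	NA	NA	NA	0	0	0
5	chrZ:27236000-27245000	9000	ENSGALG00000048068	NA	NA	NA	NA	NA	NA	0	0	0
5	chrZ:27236000-27245000	9000	X603141644	NA	1660.78	559.76	3042.07	1.40E-07	0.18	9	9	0
5	chrZ:27236000-27245000	9000	X603862378	NA	170.5	110.64	245.6	4.60E-09	0.45	9	9	0
6	chrZ:27257000-27267000	10000	ENSGALG00000050012	NA	NA	NA	NA	NA	NA	0	0	0
6	chrZ:27257000-27267000	10000	ENSGALG00000048068	NA	NA	NA	NA	NA	NA	0	0	0
6	chrZ:27257000-27267000	10000	X603141644	NA	1660.78	559.76	3042.07	1.40E-07	0.18	10	10	0
6	chrZ:27257000-27267000	10000	X603862378	NA	170.5	110.64	245.6	4.60E-09	0.45	10	10	0
7	chrZ:27324000-27350000	26000	ENSGALG00000048068	NA	NA	NA	NA	NA	NA	0	0	0
7	chrZ:27324000-27350000	26000	ENSGALG00000051419	NA	NA	NA	NA	NA	NA	0	0	0
7	chrZ:27324000-27350000	26000	X603141644	NA	1660.78	559.76	3042.07	1.40E-07	0.18	26	26	0
7	chrZ:27324000-27350000	26000	X603862378	NA	170.5	110.64	245.6	4.60E-09	0.45	26	26	0
8	chrZ:27351000-27368000	17000	ENSGALG00000051419	NA	NA	NA	NA	NA	NA	0	0	0
8	chrZ:27351000-27368000	17000	X603141644	NA	1660.78	559.76	3042.07	1.40E-07	0.18	17	17	0
8	chrZ:27351000-27368000	17000	X603862378	NA	170.5	110.64	245.6	4.60E-09	0.45	16	16	0
8	chrZ:27351000-27368000	17000	ENSGALG00000014448	CDC37L1	581.96	603.15	555.38	3.90E-01	1.09	0	0	0
8	chrZ:27351000-27368000	17000	est_12	NA	31.57	31.6	31.54	1.00E+00	1	0	0	0
9	chrZ:27373000-27382000	9000	ENSGALG00000051419	NA	NA	NA	NA	NA	NA	0	0	0
9	chrZ:27373000-27382000	9000	X603141644	NA	1660.78	559.76	3042.07	1.40E-07	0.18	9	9	0
9	chrZ:27373000-27382000	9000	X603862378	NA	170.5	110.64	245.6	4.60E-09	0.45	5	5	0
9	chrZ:27373000-27382000	9000	ENSGALG00000014448	CDC37L1	581.96	603.15	555.38	3.90E-01	1.09	0	0	0
9	chrZ:27373000-27382000	9000	ENSGALG00000014447	AK3	2604.12	2819.37	2334.08	2.00E-02	1.21	0	0	0
9	chrZ:27373000-27382000	9000	est_12	NA	31.57	31.6	31.54	1.00E+00	1	0	0	0
9	chrZ:27373000-27382000	9000	est_13	NA	3094.4	3287.64	2851.97	1.10E-03	1.15	0	0	0
9	chrZ:27373000-27382000	9000	est_14	NA	263.39	277.56	245.86	9.80E-01	1.13	0	0	0
10	chrZ:27385000-27392000	7000	ENSGALG00000051419	NA	NA	NA	NA	NA	NA	0	0	0
10	chrZ:27385000-27392000	7000	X603141644	NA	1660.78	559.76	3042.07	1.40E-07	0.18	7	7	0
10	chrZ:27385000-27392000	7000	X603862378	NA	170.5	110.64	245.6	4.60E-09	0.45	0	0	0
10	chrZ:27385000-27392000	7000	ENSGALG00000014448	CDC37L1	581.96	603.15	555.38	3.90E-01	1.09	0	0	0
10	chrZ:27385000-27392000	7000	ENSGALG00000014447	AK3	2604.12	2819.37	2334.08	2.00E-02	1.21	0	0	0
10	chrZ:27385000-27392000	7000	est_12	NA	31.57	31.6	31.54	1.00E+00	1	0	0	0
10	chrZ:27385000-27392000	7000	est_13	NA	3094.4	3287.64	2851.97	1.10E-03	1.15	0	0	0
10	chrZ:27385000-27392000	7000	est_14	NA	263.39	277.56	245.86	9.80E-01	1.13	0	0	0
11	chrZ:27393000-27399000	6000	ENSGALG00000051419	NA	NA	NA	NA	NA	NA	0	0	0
11	chrZ:27393000-27399000	6000	X603141644	NA	1660.78	559.76	3042.07	1.40E-07	0.18	6	6	0
11	chrZ:27393000-27399000	6000	X603862378	NA	170.5	110.64	245.6	4.60E-09	0.45	5	5	0
11	chrZ:27393000-27399000	6000	ENSGALG00000014448	CDC37L1	581.96	603.15	555.38	3.90E-01	1.09	0	0	0
11	chrZ:27393000-27399000	6000	ENSGALG00000014447	AK3	2604.12	2819.37	2334.08	2.00E-02	1.21	0	0	0
11	chrZ:27393000-27399000	6000	est_12	NA	31.57	31.6	31.54	1.00E+00	1	0	0	0
11	chrZ:27393000-27399000	6000	est_13	NA	3094.4	3287.64	2851.97	1.10E-03	1.15	0	0	0
11	chrZ:27393000-27399000	6000	est_14	NA	263.39	277.56	245.86	9.80E-01	1.13	0	0	0
11	chrZ:27393000-27399000	6000	ENSGALG00000053602	NA	NA	NA	NA	NA	NA	0	0	0
12	chrZ:31666000-31672000	6000	ENSGALG00000054940	NA	NA	NA	NA	NA	NA	0	0	0
12	chrZ:31666000-31672000	6000	ENSGALG00000027428	ZDHHC21	600.52	639.38	551.76	3.30E-01	1.16	1	0	1
12	chrZ:31666000-31672000	6000	est_15	NA	34.7	34.97	34.35	1.00E+00	1.02	0	0	0
12	chrZ:31666000-31672000	6000	ENSGALG00000049291	NA	NA	NA	NA	NA	NA	0	0	0
12	chrZ:31666000-31672000	6000	ENSGALG00000005434	CER1	74.21	74.32	74.07	1.00E+00	1	0	0	0
13	chrZ:35555000-35561000	6000	ENSGALG00000015138	ABHD17B	1098.95	1208.65	961.34	1.10E-04	1.26	6	0	6
13	chrZ:35555000-35561000	6000	ENSGALG00000026001	C9orf85	850.04	965.8	704.82	8.20E-03	1.37	5	0	5
14	chrZ:38550000-38557000	7000	ENSGALG00000052137	NA	NA	NA	NA	NA	NA	0	0	0
14	chrZ:38550000-38557000	7000	est_16	NA	182.51	202	158.05	1.50E-02	1.28	7	0	7
14	chrZ:38550000-38557000	7000	ENSGALG00000015184	TLE4	1149.41	1253.05	1019.39	9.30E-01	1.23	0	0	0
14	chrZ:38550000-38557000	7000	est_17	NA	656.46	668.55	641.3	1.00E+00	1.04	0	0	0
14	chrZ:38550000-38557000	7000	est_18	NA	111.28	118.01	102.83	1.00E+00	1.15	0	0	0
15	chrZ:52025000-52031000	6000	ENSGALG00000015311	RNF38	5893.88	6385.04	5277.7	1.30E-03	1.21	3	0	3
15	chrZ:52025000-52031000	6000	ENSGALG00000015315	TRIM14	247.75	265.69	225.9	3.50E-01	1.18	0	0	0
15	chrZ:52025000-52031000	6000	ENSGALG00000015320	NANS	3893.37	4087.64	3649.65	1.00E-03	1.12	5	0	5
16	chrZ:52073000-52079000	6000	ENSGALG00000015311	RNF38	5893.88	6385.04	5277.7	1.30E-03	1.21	5	0	5
16	chrZ:52073000-52079000	6000	ENSGALG00000015315	TRIM14	247.75	265.69	225.9	3.50E-01	1.18	0	0	0
16	chrZ:52073000-52079000	6000	ENSGALG00000015320	NANS	3893.37	4087.64	3649.65	1.00E-03	1.12	6	0	6
16	chrZ:52073000-52079000	6000	ENSGALG00000015326	CLTA	23451.7	25526.3	20849.1	2.30E-07	1.22	6	0	6
16	chrZ:52073000-52079000	6000	est_19	NA	24880.1	27004.9	22214.3	1.80E-07	1.22	6	0	6
16	chrZ:52073000-52079000	6000	est_20	NA	199.25	244.38	142.62	1.90E-03	1.71	5	0	5
19	chrZ:58494000-58500000	6000	ENSGALG00000050984	NA	NA	NA	NA	NA	NA	0	0	0
19	chrZ:58494000-58500000	6000	est_21	NA	74.27	75.22	73.09	1.00E+00	1.03	0	0	0
19	chrZ:58494000-58500000	6000	ENSGALG00000027907	NR2F1	NA	NA	NA	NA	NA	0	0	0
19	chrZ:58494000-58500000	6000	ENSGALG00000050798	NA	NA	NA	NA	NA	NA	0	0	0
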