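window_id	chrom	start	avg	median	avg_male	avg_female	pvalue	mf_ratio	mf_runavg	fhm_block
chrZ_30195000	chrZ	30195000	80.17	70.52	71.05	91.62	1.41E-02	0.78	1.26	1
chrZ_30196000	chrZ	30196000	52.73	48.01	42.69	65.32	2.07E-05	0.65	1.25	1
chrZ_30197000	chrZ	30197000	78.65	73.65	70.17	89.28	7.32E-03	0.79	1.23	1
chrZ_30198000	chrZ	30198000	66.48	60.78	56.40	79.13	2.62E-04	0.71	1.20	1
chrZ_30199000	chrZ	30199000	69.29	61.94	61.36	79.25	1.64E-02	0.77	1.18	1
chrZ_30200000	chrZ	30200000	32.70	30.17	28.75	37.65	1.92E-02	0.76	1.16	1
chrZ_42633000	chrZ	42633000	57.33	50.01	49.31	67.39	4.38E-03	0.73	1.53	2
chrZ_42634000	chrZ	42634000	81.07	76.75	67.55	98.04	1.25E-05	0.69	1.50	2
chrZ_42635000	chrZ	42635000	64.55	59.29	54.35	77.36	1.73E-04	0.70	1.46	2
chrZ_42636000	chrZ	42636000	64.06	59.41	55.99	74.20	4.46E-03	0.75	1.43	2
chrZ_42637000	chrZ	42637000	87.94	82.79	77.66	100.85	1.71E-03	0.77	1.43	2
chrZ_42638000	chrZ	42638000	77.38	73.39	69.06	87.82	2.81E-02	0.79	1.42	2
chrZ_49068000	chrZ	49068000	33.32	33.10	29.34	38.32	9.41E-04	0.77	1.43	3
chrZ_49069000	chrZ	49069000	103.06	93.79	88.37	121.50	2.15E-04	0.73	1.41	3
chrZ_49070000	chrZ	49070000	73.53	64.76	61.14	89.06	1.55E-04	0.69	1.38	3
chrZ_49071000	chrZ	49071000	82.15	76.27	69.69	97.78	2.40E-04	0.71	1.34	3
chrZ_49072000	chrZ	49072000	109.91	100.09	91.25	133.31	1.73E-06	0.68	1.31	3
chrZ_49073000	chrZ	49073000	51.46	46.02	42.84	62.27	4.95E-04	0.69	1.27	3
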