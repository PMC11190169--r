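soc	soc_code	a	b	c	d	ror	ror_low	ror_high	prr	chi2	p_value	ic	ic025	ebgm	ebgm05
Injury, poisoning and procedural complications	10022117	10634	9409	154120	1730318	12.69	12.34	13.05	6.49	50542.75	0.00E+00	2.62	2.54	6.13	5.96
General disorders and administration site conditions	10018065	7851	12192	146800	1737638	7.62	7.41	7.85	5.03	26175.61	0.00E+00	2.27	2.18	4.82	4.69
Gastrointestinal disorders	10017947	5759	14284	92690	1791748	7.79	7.55	8.04	5.84	22943.94	0.00E+00	2.47	2.37	5.56	5.39
Metabolism and nutrition disorders	10027433	1809	18234	53677	1830761	3.38	3.22	3.55	3.17	2675.34	0.00E+00	1.63	1.47	3.1	2.95
Investigations	10022891	1674	18369	29089	1855349	5.81	5.52	6.12	5.41	5784.67	0.00E+00	2.37	2.2	5.17	4.91
Endocrine disorders	10014698	69	19974	1518	1882920	4.28	3.37	5.46	4.27	165.64	6.63E-38	2.05	1.25	4.13	3.24
Eye disorders	10015919	68	19975	709	1883729	9.04	7.05	11.6	9.02	442.48	3.12E-98	3.06	2.24	8.32	6.48
Neoplasms benign, malignant and unspecified (incl cysts and polyps)	10029104	37	20006	988	1883450	3.53	2.54	4.9	3.52	64.41	1.01E-15	1.78	0.72	3.43	2.47
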