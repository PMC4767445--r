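rsid	chrom	gene	effect_allele	eaf	control_eaf	beta_ratio	bp_weight	gwas_p	glioma_or
rs11125529	2	ACYP2	A	0.14	0.13	0.056	66.9	4.5e-08	1.07
rs10936599	3	TERC	C	0.75	0.76	0.097	117.3	2.5e-31	1.14
rs7675998	4	NAF1	G	0.78	0.77	0.074	89.7	4.3e-16	1.01
rs2736100	5	TERT	C	0.49	0.51	0.078	94.2	4.4e-19	1.39
rs9420907	10	OBFC1	C	0.14	0.14	0.069	82.8	6.9e-11	1.18
rs3027234	17	CTC1	C	0.79	0.78	0.021	25.2	2.0e-02	1.14
rs8105767	19	ZNF208	G	0.29	0.29	0.048	57.6	1.1e-09	1.04
rs755017	20	RTEL1	G	0.13	0.12	0.062	74.1	6.7e-09	1.05
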