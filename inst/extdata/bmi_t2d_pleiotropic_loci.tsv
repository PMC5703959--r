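snp_id	role	gene	chrom	p_bmi	p_t2d	cfdr_bmi_t2d	cfdr_t2d_bmi	conj_fdr
rs9930506	intronic	FTO	16	2.52E-124	1.90E-10	1.01E-123	1.90E-10	1.90E-10
rs10787472	intronic	TCF7L2	10	3.25E-07	1.30E-36	3.25E-07	6.63E-35	3.25E-07
rs2881654	intronic	PPARG	3	1.40E-06	3.40E-09	4.19E-06	7.82E-08	4.19E-06
rs849135	intronic	JAZF1	7	1.45E-05	1.70E-09	3.85E-05	7.08E-08	3.85E-05
rs4481184	intronic	IGF2BP2	3	0.0002524	4.50E-22	0.0003786	6.55E-20	0.0003786
rs7141420	intronic	NRXN3	14	8.66E-15	0.00025	4.68E-13	0.001125	0.001125
rs6795735	ncRNA_intronic	ADAMTS9-AS2	3	2.92E-05	2.00E-04	0.000555	0.00604	0.00604
rs12895330	intergenic	AKAP6,NPAS3	14	9.72E-05	0.00021	0.0016041	0.007245	0.007245
rs2334255	UTR3	GIPR	19	0.0008051	0.00034	0.0114503	0.0176422	0.0176422
rs1783598	intronic	FCHSD2	11	0.0003666	0.00052	0.0064359	0.0193556	0.0193556
rs12245680	intronic	TCF7L2	10	0.01444	1.10E-09	0.02527	6.70E-07	0.02527
rs17584208	intergenic	PSRC1,MYBPHL	1	4.58E-06	0.0016	0.000306	0.02976	0.02976
rs2488071	intergenic	HHEX,EXOC6	10	0.006642	4.70E-06	0.032103	0.0011194	0.032103
rs11979110	intergenic	KLF14,MIR29A	7	0.00288	9.70E-05	0.03456	0.0140973	0.03456
rs1473	intronic	PUM1	1	0.0004889	0.00092	0.0114403	0.03542	0.03542
rs10898868	intronic	ARAP1	11	0.002589	0.00044	0.0370227	0.03608	0.0370227
rs1996023	intergenic	GNPDA2,GABRG1	4	1.11E-20	0.025	1.93E-17	0.0375	0.0375
rs825461	intronic	ZNF664,FAM101A	12	0.0003917	0.0013	0.0114376	0.04472	0.04472
rs16945088	intronic	FTO	16	5.30E-09	0.0072	1.48E-06	0.045	0.045
rs9540493	intergenic	LOC10272396,LINC01052	13	3.95E-09	0.0057	1.22E-06	0.0456	0.0456
rs4238585	intergenic	GPR139,GP2	16	1.12E-08	0.0069	3.02E-06	0.0483	0.0483
rs12454712	intronic	BCL2	18	6.04E-06	0.0034	0.0004955	0.0485714	0.0485714
rs4474658	intergenic	C2CD4A,C2CD4B	15	0.009024	9.60E-06	0.0489874	0.0023849	0.0489874
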