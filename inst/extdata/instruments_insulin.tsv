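snp	gene	effect_allele	beta	p	note
rs1530559	YSK4	A	0.015	3.4e-8
rs2745353	RSPO3	T	0.014	5.5e-9
rs2820436	LYPLAL1	C	0.015	4.4e-9
rs2972143	IRS1	G	0.014	3.2e-8
rs4865796	ARL15	A	0.015	2.1e-8
rs731839	PEPD	G	0.015	1.7e-8
rs983309	PPP1R3B	T	0.029	3.8e-14
rs1167800	HIP1	A	0.016	2.6e-9	pleiotropy_bmi
rs7903146	TCF7L2	C	0.018	6.1e-11	pleiotropy_bmi
rs1421085	FTO	C	0.020	1.9e-15	curated_fto
rs9884482	TET2	C	0.017	1.4e-11	pleiotropy_alcohol
rs10195252	GRB14	T	0.016	4.9e-10	pleiotropy_alcohol
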