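snp	gene	effect_allele	beta	p	note
rs17036328	PPARG	T	0.021	3.6e-12
rs2126259	PPP1R3B	T	0.024	3.3e-13
rs2943645	IRS1	T	0.019	2.3e-19
rs3822072	FAM13A1	A	0.012	1.8e-8	men_pleiotropy_bmi
rs459193	ANKRD55	G	0.015	1.2e-10
rs4846565	LYPLAL1	G	0.013	1.8e-9
rs4865796	ARL15	A	0.015	2.2e-12
rs6822892	PDGFC	A	0.014	2.6e-10
rs731839	PEPD	G	0.015	5.1e-12
rs6912327	C6orf107	T	0.017	2.3e-8	pleiotropy_bmi
rs974801	TET2	G	0.014	3.3e-11	pleiotropy_alcohol
rs10195252	GRB14	T	0.017	1.3e-16	pleiotropy_alcohol
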