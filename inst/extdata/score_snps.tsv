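snp	risk_allele	weight
rs4846565	G	1
rs10195252	T	1
rs2943645	T	1
rs17036328	T	1
rs3822072	A	1
rs6822892	A	1
rs4865796	A	1
rs459193	G	1
rs2745353	T	1
rs731839	G	1
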