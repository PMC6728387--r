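snp	confounder	stratum	p
rs10195252	alcohol	overall	9.4e-7
rs9884482	alcohol	overall	2.3e-6
rs1167800	bmi	overall	8.7e-13
rs7903146	bmi	overall	9.8e-7
rs974801	alcohol	overall	8.5e-7
rs6912327	bmi	overall	1.6e-14
rs3822072	bmi	men	5.5e-6
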