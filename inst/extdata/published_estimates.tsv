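outcome	source	sex	n_cases	exposure	or	ci_low	ci_high	p
mi	ukb	overall	14442	insulin	2.87	1.30	6.33	0.009
mi	ukb	overall	14442	insulin_bmi_adjusted	2.63	1.36	5.07	0.004
mi	ukb	overall	14442	grs	3.23	1.88	5.56	2.4e-5
mi	ukb	men	11182	insulin	4.27	1.60	11.3	0.004
mi	ukb	men	11182	insulin_bmi_adjusted	3.60	1.46	8.83	0.005
mi	ukb	men	11182	grs	4.17	2.24	7.77	6.9e-6
mi	ukb	women	3260	insulin	0.80	0.23	2.84	0.73
mi	ukb	women	3260	insulin_bmi_adjusted	0.96	0.30	3.09	0.95
mi	ukb	women	3260	grs	1.41	0.46	4.29	0.55
mi	cardiogram	overall	42561	insulin	1.90	1.04	3.49	0.04
mi	cardiogram	overall	42561	insulin_bmi_adjusted	2.20	1.08	4.50	0.03
mi	meta	overall	57003	insulin	2.21	1.37	3.58	0.001
mi	meta	overall	57003	insulin_bmi_adjusted	2.42	1.49	3.93	0.0003
angina	ukb	overall	21939	insulin	2.05	0.87	4.83	0.10
angina	ukb	overall	21939	insulin_bmi_adjusted	1.90	0.92	3.94	0.08
angina	ukb	overall	21939	grs	2.87	1.84	4.48	3.7e-6
angina	ukb	men	14331	insulin	2.93	1.27	6.73	0.01
angina	ukb	men	14331	insulin_bmi_adjusted	2.74	1.21	6.19	0.02
angina	ukb	men	14331	grs	3.56	2.04	6.22	8.3e-6
angina	ukb	women	7608	insulin	1.10	0.38	3.18	0.87
angina	ukb	women	7608	insulin_bmi_adjusted	1.00	0.46	2.19	1.00
angina	ukb	women	7608	grs	1.96	0.93	4.12	0.08
heart_failure	ukb	overall	5537	insulin	0.98	0.37	2.61	0.97
heart_failure	ukb	overall	5537	insulin_bmi_adjusted	1.18	0.45	3.14	0.74
heart_failure	ukb	overall	5537	grs	1.00	0.42	2.35	1.00
heart_failure	ukb	men	3935	insulin	1.17	0.30	4.64	0.82
heart_failure	ukb	men	3935	insulin_bmi_adjusted	1.90	0.62	5.82	0.26
heart_failure	ukb	men	3935	grs	1.71	0.62	4.74	0.30
heart_failure	ukb	women	1602	insulin	0.64	0.06	7.18	0.72
heart_failure	ukb	women	1602	insulin_bmi_adjusted	0.37	0.03	4.05	0.41
heart_failure	ukb	women	1602	grs	0.28	0.06	1.34	0.11
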