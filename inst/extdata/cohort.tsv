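key	value
n_total	392010
male_fraction	0.456
external_mi_cases	42561
external_noncases	123504
instrument_r2	0.01
exposure_gwas_n	108557
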