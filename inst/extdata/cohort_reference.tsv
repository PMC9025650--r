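group	n	age_mean	age_sd	pct_female	hba1c_mean	hba1c_sd	bmi_mean	bmi_sd	selfreport_dx_diabetes	selfreport_rx_diabetes
control	142	45.3	8.4	75	5.34	0.26	31.91	8.45	0	0
prediabetic	274	46.7	7.3	75	5.96	0.21	33.73	7.91	22	0
diabetic	90	52.1	9.7	78	8.02	1.84	37.85	9.53	51	3
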