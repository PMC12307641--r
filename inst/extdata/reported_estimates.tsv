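analysis	group	or	ci_low	ci_high	reported_p
treatment	juntendo_rt	2.55	1.08	6.50	0.04
treatment	juntendo_endocrine	1.57	0.67	3.91	0.31
treatment	juntendo_surgery	0.61	0.22	1.62	0.33
meta	bbj_prostate	1.44	1.01	2.04	0.04
meta	bbj_overall	1.48	1.11	1.98	0.01
time_strata	juntendo_lt1y	3.11	0.63	12.15	0.12
time_strata	juntendo_ge1y	2.45	1.00	6.41	0.06
time_strata	bbj_lt1y	1.66	1.18	2.32	0.0034
time_strata	bbj_ge1y	1.38	0.90	2.13	0.14
modality	imrt	3.05	1.26	7.95	0.016
modality	brachytherapy	1.46	0.30	5.61	0.60
dose_per_gy	imrt	1.014	1.002	1.027	0.024
dose_per_gy	brachytherapy	1.003	0.993	1.011	0.58
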