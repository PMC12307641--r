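cohort	site	n	n_mloy	n_rt	n_mloy_rt
juntendo	prostate	348	28	NA	NA
bbj1	prostate	5090	109	925	23
bbj1	lung	2637	32	426	7
bbj1	colorectal	4303	55	98	1
bbj1	gastric	4793	52	69	1
bbj2	prostate	5582	69	1848	24
bbj2	lung	1800	20	451	7
bbj2	colorectal	3910	41	325	4
bbj2	gastric	2731	35	99	2
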