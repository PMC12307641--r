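characteristic	category	n_mloy	n_non_mloy	reported_p
ipsa	<10	16	191	0.82
ipsa	10-19.9	7	64	0.82
ipsa	>=20	5	57	0.82
gleason	<=6	6	81	0.14
gleason	7	8	138	0.14
gleason	>=8	13	89	0.14
t_stage	T1	4	41	0.92
t_stage	T2	18	202	0.92
t_stage	>=T3	6	76	0.92
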