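material	density_g_cm3	z_over_a
water	1	0.55508
beryllium	1.848	0.44384
aluminium	2.699	0.48181
air	0.001205	0.49919
tungsten	19.3	0.4025
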