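snp_id	trait	chrom	pos	p	major_af	effect_direction
s01	E10	1	115000	5e-06	0.70	-1
s02	E10	1	175000	1e-04	0.80	-1
s03	E10	1	205000	2e-05	0.50	-1
s04	E10	1	235000	8e-05	0.75	1
s05	E10	1	109999	1e-06	0.90	-1
s06	L10	1	705000	3e-05	0.60	1
s07	L10	1	755000	9e-05	0.58	-1
s08	LT50	2	65000	5e-05	0.90	-1
s09	LT50	2	152000	2e-05	0.90	1
s10	E10	1	355000	2e-02	0.85	-1
s11	L10	1	645000	1e-05	0.90	1
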