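condition	strain	ratio	value	sd
normoxic	expressing	b	0.44	0.02
normoxic	expressing	d	0.50	0.09
oxygen_limited	expressing	a	0.43	0.03
oxygen_limited	expressing	c	0.63	0.03
oxygen_limited	expressing	d	0.23	0.06
hypoxic	expressing	a	0.55	0.03
hypoxic	expressing	c	0.64	0.04
hypoxic	expressing	d	0.15	0.07
normoxic	control	b	0.42	0.02
normoxic	control	d	0.39	0.09
oxygen_limited	control	a	0.44	0.03
oxygen_limited	control	c	0.66	0.03
oxygen_limited	control	d	0.32	0.08
hypoxic	control	a	0.51	0.03
hypoxic	control	c	0.66	0.04
hypoxic	control	d	0.15	0.06
normoxic	expressing	r5p_from_t3p_s7p_tkt	0.71	0.02
oxygen_limited	expressing	r5p_from_t3p_s7p_tkt	0.78	0.02
hypoxic	expressing	r5p_from_t3p_s7p_tkt	0.70	0.02
normoxic	control	r5p_from_t3p_s7p_tkt	0.66	0.02
oxygen_limited	control	r5p_from_t3p_s7p_tkt	0.70	0.02
hypoxic	control	r5p_from_t3p_s7p_tkt	0.62	0.02
normoxic	expressing	r5p_from_e4p_tal	0.44	0.02
oxygen_limited	expressing	r5p_from_e4p_tal	0.24	0.02
hypoxic	expressing	r5p_from_e4p_tal	0.23	0.02
normoxic	control	r5p_from_e4p_tal	0.40	0.02
oxygen_limited	control	r5p_from_e4p_tal	0.29	0.02
hypoxic	control	r5p_from_e4p_tal	0.24	0.02
normoxic	expressing	ser_from_gly_c1	0.61	0.04
oxygen_limited	expressing	ser_from_gly_c1	0.68	0.04
hypoxic	expressing	ser_from_gly_c1	0.68	0.04
normoxic	control	ser_from_gly_c1	0.62	0.04
oxygen_limited	control	ser_from_gly_c1	0.69	0.04
hypoxic	control	ser_from_gly_c1	0.72	0.04
normoxic	expressing	gly_from_co2_c1	0.10	0.04
oxygen_limited	expressing	gly_from_co2_c1	0.13	0.03
hypoxic	expressing	gly_from_co2_c1	0.13	0.03
normoxic	control	gly_from_co2_c1	0.06	0.04
oxygen_limited	control	gly_from_co2_c1	0.12	0.03
hypoxic	control	gly_from_co2_c1	0.10	0.03
normoxic	expressing	pep_from_oaa_pepck	0.00	0.04
oxygen_limited	expressing	pep_from_oaa_pepck	0.00	0.08
hypoxic	expressing	pep_from_oaa_pepck	0.00	0.10
normoxic	control	pep_from_oaa_pepck	0.02	0.05
oxygen_limited	control	pep_from_oaa_pepck	0.00	0.10
hypoxic	control	pep_from_oaa_pepck	0.05	0.11
oxygen_limited	expressing	oaa_mit_from_pep	0.32	0.02
hypoxic	expressing	oaa_mit_from_pep	0.44	0.02
oxygen_limited	control	oaa_mit_from_pep	0.35	0.02
hypoxic	control	oaa_mit_from_pep	0.41	0.02
normoxic	expressing	oaa_cyt_fum_reversible	0.63	0.11
oxygen_limited	expressing	oaa_cyt_fum_reversible	0.07	0.05
hypoxic	expressing	oaa_cyt_fum_reversible	0.10	0.05
normoxic	control	oaa_cyt_fum_reversible	0.63	0.11
oxygen_limited	control	oaa_cyt_fum_reversible	0.11	0.04
hypoxic	control	oaa_cyt_fum_reversible	0.09	0.04
normoxic	expressing	malic_enzyme_upper	0.01	0.04
normoxic	control	malic_enzyme_upper	0.01	0.06
normoxic	expressing	malic_enzyme_lower	0.01	0.02
normoxic	control	malic_enzyme_lower	0.00	0.03
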