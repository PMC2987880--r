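condition	o2_percent	quantity	value	sd	units
normoxic	21	dilution_rate	0.1	0.002	1/h
normoxic	21	biomass	23.98	1.16	g/L
normoxic	21	biomass_yield	0.47	0.02	g/g
normoxic	21	fab_specific	0.22	0.01	mg/gDCW
normoxic	21	ethanol	0	0	g/L
normoxic	21	glycerol	0	0	g/L
normoxic	21	arabitol	0	0	g/L
normoxic	21	OUR	2.23	0.03	mmol/gDCW/h
normoxic	21	CER	2.34	0.04	mmol/gDCW/h
oxygen_limited	11	dilution_rate	0.1	0.002	1/h
oxygen_limited	11	biomass	22.54	1.83	g/L
oxygen_limited	11	biomass_yield	0.45	0.01	g/g
oxygen_limited	11	fab_specific	0.38	0.01	mg/gDCW
oxygen_limited	11	ethanol	0.89	0.16	g/L
oxygen_limited	11	glycerol	0	0	g/L
oxygen_limited	11	arabitol	0.90	0.22	g/L
oxygen_limited	11	OUR	2.26	0.16	mmol/gDCW/h
oxygen_limited	11	CER	2.57	0.16	mmol/gDCW/h
hypoxic	8	dilution_rate	0.1	0.002	1/h
hypoxic	8	biomass	12.58	1.94	g/L
hypoxic	8	biomass_yield	0.25	0.01	g/g
hypoxic	8	fab_specific	0.54	0.02	mg/gDCW
hypoxic	8	ethanol	6.85	0.33	g/L
hypoxic	8	glycerol	0	0	g/L
hypoxic	8	arabitol	2.88	0.31	g/L
hypoxic	8	OUR	4.14	0.21	mmol/gDCW/h
hypoxic	8	CER	5.62	0.32	mmol/gDCW/h
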