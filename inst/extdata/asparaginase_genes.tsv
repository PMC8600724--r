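protein_id	amino_acids	log2_fold_change	p_value	adjusted_p_value	product	pfam
H0G86_011901-T1	571	7.61	1.45e-05	6.99e-05	Putative L-asparaginase	PF07690
H0G86_012728-T1	522	3.66	3.30e-16	6.31e-15	Asparaginase	PF00710;PF17763
H0G86_013185-T1	362	1.70	3.80e-05	1.69e-04	hypothetical protein	PF06089
H0G86_012144-T1	460	-3.90	8.70e-15	1.46e-13	hypothetical protein	PF01112
H0G86_001521-T1	614	-0.34	0.082	0.15	hypothetical protein	PF01112
H0G86_011897-T3	840	1.00	0.04	0.08	hypothetical protein	PF01112
H0G86_012090-T1	361	0.50	0.16	0.26	Asparaginase	PF01112
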