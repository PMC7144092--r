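genotype	total	balancer_class	mutant_class	total_tested	sterile	fertile
para_Shu/Y; +/+	73	67	6	43	42	1
para_Shu/Y; GstS1_M26/+	121	83	38	45	28	17
para_Shu/Y; GstS1_M26/GstS1_M26	145	68	77	44	27	17
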