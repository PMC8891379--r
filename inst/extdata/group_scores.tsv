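product_type	statistic	mean	sd	min	max
rice-based	sigma_pah16	3.28	0.32	3.05	3.50
rice-based	pah4	0.47	0.14	0.37	0.57
wheat-based	sigma_pah16	4.75	0.27	4.56	4.94
wheat-based	pah4	0.82	0.08	0.76	0.88
mixed wheat and rice-based	sigma_pah16	3.10	0.56	2.70	3.49
mixed wheat and rice-based	pah4	0.59	0.31	0.37	0.81
mixed wheat and honey-based	sigma_pah16	3.31	0.65	2.85	3.77
mixed wheat and honey-based	pah4	0.47	0.14	0.37	0.57
mixed wheat and date-based	sigma_pah16	3.03	0.41	2.74	3.32
mixed wheat and date-based	pah4	0.63	0.16	0.51	0.74
mixed almond porridge and fruit-based	sigma_pah16	3.74	0.18	3.61	3.87
mixed almond porridge and fruit-based	pah4	0.86	0.11	0.78	0.93
mixed wheat and fruit-based	sigma_pah16	3.17	0.28	2.97	3.37
mixed wheat and fruit-based	pah4	0.73	0.24	0.56	0.90
mixed 5 cereal-based	sigma_pah16	5.06	0.68	4.58	5.54
mixed 5 cereal-based	pah4	0.98	0.02	0.97	0.98
almond porridge-based	sigma_pah16	4.16	0.08	4.10	4.22
almond porridge-based	pah4	0.95	0.06	0.90	0.99
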