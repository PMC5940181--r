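network	n_nodes	n_edges	avg_degree	diameter	avg_path_length	clustering	giant_component
DrugBank	2551	577712	452.93	6	2.27	0.52	1.00
KEGG	1194	52609	88.12	7	2.51	0.37	1.00
NDF-RT	701	8044	22.95	8	3.30	0.16	0.99
SemMedDB	1688	37287	44.18	6	2.58	0.44	1.00
Twosides	340	19020	111.88	3	1.68	0.83	1.00
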