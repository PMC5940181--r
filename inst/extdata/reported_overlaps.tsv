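network1	network2	shared	proportion_reported
DrugBank	DrugBank	296656	NA
KEGG	KEGG	33474	NA
NDF-RT	NDF-RT	4010	NA
SemMedDB	SemMedDB	28924	NA
Twosides	Twosides	17219	NA
DrugBank	KEGG	11961	0.36
DrugBank	NDF-RT	1790	0.45
DrugBank	SemMedDB	8603	0.30
DrugBank	Twosides	7411	0.43
KEGG	NDF-RT	576	0.14
KEGG	SemMedDB	1077	0.04
KEGG	Twosides	691	0.04
NDF-RT	SemMedDB	390	0.10
NDF-RT	Twosides	199	0.05
SemMedDB	Twosides	1396	0.08
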