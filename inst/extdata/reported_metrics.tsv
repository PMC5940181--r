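network	classifier	subset	precision	recall	f1	auroc	aupr
DrugBank	unsupervised	train	0.63	0.68	0.65	0.93	0.70
DrugBank	unsupervised	test	0.63	0.68	0.65	0.93	0.70
KEGG	unsupervised	train	0.28	0.63	0.38	0.91	0.32
KEGG	unsupervised	test	0.28	0.64	0.39	0.91	0.35
NDF-RT	unsupervised	train	0.09	0.58	0.15	0.83	0.10
NDF-RT	unsupervised	test	0.08	0.56	0.14	0.84	0.11
SemMedDB	unsupervised	train	0.16	0.80	0.27	0.93	0.45
SemMedDB	unsupervised	test	0.17	0.83	0.28	0.95	0.48
Twosides	unsupervised	train	0.96	0.30	0.46	0.90	0.83
Twosides	unsupervised	test	0.96	0.30	0.45	0.89	0.82
DrugBank	DT	train	0.84	0.56	0.67	0.84	0.64
DrugBank	kNN	train	0.86	0.70	0.77	0.98	0.89
DrugBank	SVM	train	0.83	0.59	0.69	0.93	0.78
DrugBank	RF	train	0.84	0.56	0.67	1.00	1.00
DrugBank	GBM	train	0.83	0.65	0.73	0.96	0.82
KEGG	DT	train	0.68	0.34	0.46	0.78	0.42
KEGG	kNN	train	0.76	0.40	0.53	0.98	0.67
KEGG	SVM	train	0.70	0.21	0.33	0.79	0.45
KEGG	RF	train	0.68	0.34	0.46	1.00	1.00
KEGG	GBM	train	0.71	0.42	0.53	0.95	0.60
NDF-RT	DT	train	0.77	0.17	0.28	0.72	0.25
NDF-RT	kNN	train	0.59	0.05	0.10	0.98	0.37
NDF-RT	SVM	train	0.58	0.09	0.15	0.83	0.20
NDF-RT	RF	train	0.77	0.17	0.28	0.99	0.91
NDF-RT	GBM	train	0.91	0.28	0.43	0.94	0.53
SemMedDB	DT	train	0.76	0.24	0.36	0.75	0.36
SemMedDB	kNN	train	0.74	0.31	0.43	0.98	0.59
SemMedDB	SVM	train	0.70	0.27	0.39	0.87	0.48
SemMedDB	RF	train	0.76	0.24	0.36	0.99	0.97
SemMedDB	GBM	train	0.76	0.32	0.46	0.95	0.54
Twosides	DT	train	0.88	0.84	0.86	0.93	0.86
Twosides	kNN	train	0.91	0.81	0.86	0.97	0.95
Twosides	SVM	train	0.90	0.81	0.85	0.96	0.94
Twosides	RF	train	0.88	0.84	0.86	1.00	1.00
Twosides	GBM	train	0.92	0.87	0.89	0.98	0.96
DrugBank	DT	test	0.83	0.55	0.66	0.84	0.63
DrugBank	kNN	test	0.83	0.66	0.74	0.94	0.81
DrugBank	SVM	test	0.83	0.58	0.69	0.93	0.78
DrugBank	RF	test	0.83	0.55	0.66	0.98	0.92
DrugBank	GBM	test	0.83	0.65	0.73	0.96	0.82
KEGG	DT	test	0.66	0.32	0.43	0.79	0.42
KEGG	kNN	test	0.68	0.35	0.46	0.88	0.51
KEGG	SVM	test	0.72	0.21	0.33	0.80	0.47
KEGG	RF	test	0.66	0.32	0.43	0.96	0.69
KEGG	GBM	test	0.67	0.37	0.48	0.95	0.55
NDF-RT	DT	test	0.60	0.12	0.20	0.70	0.20
NDF-RT	kNN	test	0.25	0.03	0.06	0.79	0.17
NDF-RT	SVM	test	0.56	0.07	0.13	0.87	0.21
NDF-RT	RF	test	0.60	0.12	0.20	0.91	0.36
NDF-RT	GBM	test	0.63	0.15	0.24	0.90	0.27
SemMedDB	DT	test	0.73	0.25	0.38	0.75	0.36
SemMedDB	kNN	test	0.68	0.30	0.42	0.86	0.45
SemMedDB	SVM	test	0.69	0.29	0.41	0.89	0.50
SemMedDB	RF	test	0.73	0.25	0.38	0.96	0.55
SemMedDB	GBM	test	0.68	0.31	0.43	0.96	0.53
Twosides	DT	test	0.83	0.82	0.82	0.90	0.80
Twosides	kNN	test	0.85	0.77	0.81	0.93	0.90
Twosides	SVM	test	0.86	0.80	0.83	0.95	0.92
Twosides	RF	test	0.83	0.82	0.82	0.96	0.93
Twosides	GBM	test	0.86	0.83	0.85	0.95	0.93
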