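sample_id	subtype	driver_gene	driver_vaf	assay	mgmt_score	mgmt_call	sex	age	array_call	ddpcr_call
Pyro-311	GBM_IDHwt	TERTp	0.02	PYRO	1.49	NEGATIVE	M	61	NEGATIVE	NEGATIVE
Pyro-293	GBM_IDHwt	TERTp	0.02	PYRO	6.44	NEGATIVE	F	55	EQUIVOCAL	POSITIVE
Pyro-049	GBM_IDHwt	TERTp	0.04	PYRO	5.52	NEGATIVE	M	53	POSITIVE	EQUIVOCAL
Pyro-023	GBM_IDHwt	TERTp	0.07	PYRO	3.73	NEGATIVE	F	47	NEGATIVE	QNS
Pyro-081	GBM_IDHwt	TERTp	0.10	PYRO	11.06	POSITIVE	F	69	POSITIVE	POSITIVE
Pyro-182	GBM_IDHwt	TERTp	0.10	PYRO	4.85	NEGATIVE	F	69	NEGATIVE	QNS
Pyro-083	GBM_IDHwt	TERTp	0.25	PYRO	2.97	NEGATIVE	F	46	NEGATIVE	NEGATIVE
Pyro-200	GBM_IDHwt	TERTp	0.28	PYRO	3.18	NEGATIVE	M	53	NEGATIVE	QNS
Pyro-152	GBM_IDHwt	TERTp	0.35	PYRO	4.01	NEGATIVE	F	56	NEGATIVE	NEGATIVE
Pyro-053	GBM_IDHwt	TERTp	0.44	PYRO	35.56	POSITIVE	F	69	POSITIVE	POSITIVE
Pyro-417	GBM_IDHwt	TERTp	0.49	PYRO	3.20	NEGATIVE	F	69	NEGATIVE	NEGATIVE
Pyro-243	GBM_IDHwt	TERTp	0.78	PYRO	3.03	NEGATIVE	M	61	NEGATIVE	NEGATIVE
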