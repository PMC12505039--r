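gene	variant_id	proxy_variant	proxy_r2	lung_trait	cv_trait	ea	eaf_ukb	eaf_repl	or_ukb	p_ukb	or_repl	p_two_repl
CSNK2B	rs3117578	NA	NA	FVC	HTN	G	0.85	0.86	1.05	1.0e-15	1.04	9.7e-8
CSNK2B	rs3117578	NA	NA	FVC	CHD	G	0.85	0.86	1.04	3.1e-5	1.06	2.9e-6
FARP2	rs139354822	NA	NA	FEV1_FVC	HTN	T	0.97	0.95	1.10	2.8e-9	1.06	5.3e-5
GFI1	rs6676846	NA	NA	FEV1_FVC	HTN	A	0.79	0.78	0.97	2.7e-6	0.98	1.7e-3
IGF1	rs10745941	rs5742694	0.91	FVC	HTN	T	0.76	0.77	1.03	3.7e-6	1.02	0.02
ITGB5	rs17282078	NA	NA	FVC	CHD	A	0.13	0.10	1.06	6.2e-10	1.03	0.04
KAT8	rs1978487	NA	NA	FVC	HTN	T	0.64	0.62	1.02	5.4e-5	1.01	0.06
TNS1	rs2571445	NA	NA	FVC;FEV1_FVC	HTN	A	0.39	0.44	1.02	1.5e-5	1.01	0.02
TNS1	rs2571445	NA	NA	FVC;FEV1_FVC	CHD	A	0.39	0.44	1.04	2.9e-7	1.04	3.7e-7
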