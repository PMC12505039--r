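gene	variant_id	ea	oa	lung_trait	lung_beta	lung_p	cv_trait	cv_type	cv_effect	cv_p
CLDN20	rs1969863	T	C	FVC	-9.09	2.2e-9	PP	quantitative	0.17	6.6e-9
CSNK2B	rs3117578	G	A	FVC	-17.75	8.2e-18	SBP	quantitative	0.32	5.5e-9
CSNK2B	rs3117578	G	A	FVC	-17.75	8.2e-18	HTN	case_control	1.05	1.0e-15
CSNK2B	rs3117578	G	A	FVC	-17.75	8.2e-18	CHD	case_control	1.04	3.1e-5
IGF1	rs10745941	T	C	FVC	-9.58	4.2e-8	HTN	case_control	1.03	3.7e-6
ITGB5	rs17282078	A	G	FVC	-9.32	2.1e-5	CHD	case_control	1.06	6.2e-10
KAT8	rs1978487	T	C	FVC	-9.30	1.4e-9	HTN	case_control	1.02	5.4e-5
MMP24	rs6120880	G	A	FVC	-11.35	4.8e-14	PP	quantitative	0.16	1.3e-8
MMP24	rs6120880	G	A	FVC	-11.35	4.8e-14	CIMT	quantitative	0.01	5.0e-8
TNS1	rs2571445	A	G	FVC	-11.46	3.3e-14	SBP	quantitative	0.21	1.6e-7
TNS1	rs2571445	A	G	FVC	-11.46	3.3e-14	DBP	quantitative	0.13	5.4e-9
TNS1	rs2571445	A	G	FVC	-11.46	3.3e-14	HTN	case_control	1.02	1.5e-5
TNS1	rs2571445	A	G	FVC	-11.46	3.3e-14	CHD	case_control	1.04	2.9e-7
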