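label	group	type	japonica	indica	glaberrima	glumaepatula	rufipogon	nivara	punctata	officinalis	australiensis	brachyantha	distachyon	bicolor	mays
Ty1/Copia	I	component	7.39	7.67	6.4	4.24	8.51	6.45	5.96	5.5	10.54	8.47	5.06	7.97	36.89
Ty3/Gypsy	I	component	23.37	24.04	21.93	33.83	44.69	45.52	50.46	26.91	35.72	12.39	0.12	20.44	35.38
Intact LTR	I	intact	18.31	7.97	12.06	9.4	12.83	10.38	16.67	5.26	9.18	0	0	19.4	36.12
LINE	I	component	1.15	0.85	1.24	0.75	0.68	0.82	0.75	0.19	0.11	0.48	0.84	2.94	0.25
SINE	I	component	0.54	0.54	0.62	0.3	0.25	0.27	0.06	0.2	0.03	0.13	0	0.035	0
Intact Non-LTR	I	intact	0.3	0.28	0.29	0	0.13	0.1	0	0.12	0	0	0	0.02	0
Total	I	total	33.62	33.22	30.3	39.42	54.27	53.23	58.33	39.27	48.02	22.47	6.02	33.1	72.88
MITE/Tourist	II	component	1.62	1.51	1.51	1.7	1.24	1.14	0.69	1.05	0.13	1.98	0.65	0.802	1.18
MITE/Stowaway	II	component	1.53	1.35	1.69	1.29	1.18	1.03	0	0.48	0.16	2.11	0	0.37	0
hAT	II	component	0.94	0.91	1.02	0.4	0.29	0.06	0.08	0.11	0.75	0.51	0.14	0.67	0.58
En-Spm	II	component	6.74	3.87	4.3	5.74	6.56	7.51	8.58	13.71	8.81	0.13	0	13.82	0.92
MuDR-IS905	II	component	2.5	2.31	2.2	2.38	1.36	1.44	1.64	5.99	0.59	1.12	0	0.112	2.08
Unclassified	II	component	1.98	1.71	1.91	1.8	0.86	1.31	0.64	0.29	0.77	1.18	0	0.796	0.4
Intact DNA TE	II	intact	10.48	6.01	7.55	9.05	7.02	9.02	3.49	11.17	9.53	2.04	0	6.03	1.05
Total	II	total	15.31	11.66	12.63	13.31	11.49	12.49	11.63	21.63	11.21	7.03	0.79	16.57	5.16
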