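gene	mutation	group	conservation	specificity	conjugate_specificity	expected_switch
RAC1	I33V	gtpase_swap	-0.89	5.12	5.64	TRUE
RAC1	S41A	gtpase_swap	0.92	5.12	5.53	TRUE
RAC1	A42V	gtpase_swap	0.66	5.12	5.96	TRUE
RAC1	D47G	gtpase_swap	1.54	5.12	5.54	TRUE
RAC1	W56F	gtpase_swap	2.08	5.12	5.16	TRUE
RAC1	A95E	gtpase_swap	-0.69	5.11	5.63	TRUE
RAC1	K116Q	gtpase_swap	0.86	5.12	5.54	TRUE
RAC1	A144K	gtpase_swap	0.81	4.85	5.55	TRUE
RAC1	R174L	gtpase_swap	1.40	5.12	5.54	TRUE
CDC42	V33I	gtpase_swap	0.69	6.19	6.09	TRUE
CDC42	A41S	gtpase_swap	-0.92	6.20	6.33	TRUE
CDC42	V42A	gtpase_swap	-1.07	4.81	6.18	TRUE
CDC42	G47D	gtpase_swap	-1.37	5.50	6.33	TRUE
CDC42	F56W	gtpase_swap	-1.92	5.51	6.33	TRUE
CDC42	E95A	gtpase_swap	0.79	6.19	6.08	TRUE
CDC42	Q116K	gtpase_swap	-1.20	6.20	6.33	TRUE
CDC42	K144A	gtpase_swap	-0.75	6.19	6.32	TRUE
CDC42	L174R	gtpase_swap	-1.13	6.20	6.11	TRUE
IDH1	R132C	active_site	8.41	5.34	-5.18	FALSE
IDH1	R132H	active_site	7.16	4.65	-4.20	FALSE
IDH1	R132L	active_site	9.80	6.04	-inf	FALSE
IDH1	R132S	active_site	9.80	6.04	-inf	FALSE
KRAS	G12A	recurrent	3.22	5.83	5.02	TRUE
PIK3CA	H1047L	recurrent	-1.16	5.24	5.38	TRUE
ERBB2	R678Q	recurrent	2.23	5.75	4.61	TRUE
ERBB2	V777L	recurrent	0.78	5.76	4.87	TRUE
ERBB3	V104L	recurrent	1.04	5.61	4.67	TRUE
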