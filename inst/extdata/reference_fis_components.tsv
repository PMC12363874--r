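gene	mutation	clinvar_label	conservation	specificity	fis_reported
KRAS	G12D	Pathogenic	5.05	1.98	3.52
KRAS	G12V	Pathogenic	6.08	5.14	5.61
KRAS	G12C	Pathogenic	5.89	5.83	5.86
KRAS	G13D	Pathogenic	6.31	5.97	6.14
KRAS	G12A	Pathogenic	3.22	5.83	4.53
KRAS	G12R	Pathogenic	4.79	5.83	5.31
BRAF	V600K	NA	8.35	6.97	7.66
BRAF	K601E	Pathogenic	6.45	6.97	6.71
PIK3CA	E545K	Pathogenic	7.09	5.26	6.17
PIK3CA	H1047R	Pathogenic	5.96	4.55	5.25
PIK3CA	E542K	Pathogenic	5.93	5.26	5.59
PIK3CA	H1047L	Pathogenic	-1.16	5.24	2.04
TP53	R175H	Pathogenic	6.99	4.43	5.71
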