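variable	category	unmethylated	methylated	test
gender	male	143	112	fisher
gender	female	78	44	fisher
age	le60	125	55	fisher
age	gt60	95	101	fisher
vascular_invasion	micro_or_macro	64	47	fisher
vascular_invasion	none	123	87	fisher
ishak_fibrosis	no_fibrosis	47	29	chisq
ishak_fibrosis	portal_fibrosis	16	15	chisq
ishak_fibrosis	fibrous_septa	15	15	chisq
ishak_fibrosis	nodular_incomplete_cirrhosis	4	5	chisq
ishak_fibrosis	established_cirrhosis	34	38	chisq
histological_grade	grade1	34	21	chisq
histological_grade	grade2	104	76	chisq
histological_grade	grade3	76	48	chisq
histological_grade	grade4	7	6	chisq
tnm_stage	stage1	99	76	chisq
tnm_stage	stage2	51	36	chisq
tnm_stage	stage3	51	35	chisq
tnm_stage	stage4	5	0	chisq
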