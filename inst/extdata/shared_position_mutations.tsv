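gene	aa_pos	aa1	human_aa2	human_consensus	human_coords	dbsnp	human_maf	macaque_aa1	macaque_aa2	macaque_consensus	macaque_coords	chinese_maf	indian_maf	fascicularis_maf
DRD5	330	P	Q	Likely Neutral	chr4:9784642	rs1800762	0.03	P	L	Neutral	chr5:4664928	0.12	0.00	0.00
GPR78	318	R	C	Likely Neutral	chr4:8588950	rs61746144	0.01	R	H	Neutral	chr5:197276	0.00	0.00	0.17
HTR1E	208	A	T	Likely Deleterious	chr6:87725674	rs3828741	0.01	A	S	Likely Neutral	chr4:82975291	0.00	0.03	0.00
MRGPRX1	55	R	L	Deleterious	chr11:18956168	rs55954376	0.01	R	C	Deleterious	chr14:52926663	0.00	0.24	0.00
P2RY4	168	V	M	Likely Neutral	chrX:69478973	rs1152186	0.05	V	A	Likely Neutral	chrX:69226991	0.07	0.00	0.00
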