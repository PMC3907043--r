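gene	aa_pos	aa1	aa2	consensus	human_coords	dbsnp	human_maf	macaque_coords	chinese_maf	indian_maf	fascicularis_maf
FZD6	664	A	E	Deleterious	chr8:104343607	rs12549394	0.02	chr8:105850125	0.00	0.00	0.10
GPR19	116	V	I	Likely deleterious	chr12:12815037	rs41276680	0.01	chr11:13015710	0.02	0.00	0.22
GPR44	204	V	A	Likely neutral	chr11:60620585	rs2467642	0.01	chr14:13261124	0.07	0.02	0.83
GPR78	342	R	H	Deleterious	chr4:8589023	rs9685931	0.11	chr5:197204	0.05	0.00	0.00
GPR98	194	P	H	Deleterious	chr5:89920969	rs61745498	0.02	chr6:86859930	0.00	0.05	0.00
GPR146	266	V	M	Deleterious	chr7:1097947	rs55677825	0.01	chr3:38980764	0.14	0.00	0.00
GPR153	209	R	H	Neutral	chr1:6313938	rs12735670	0.31	chr1:9260385	0.10	0.00	0.00
GPR156	798	R	H	Likely neutral	chr3:119885931	rs115365859	0.01	chr2:40203636	0.00	0.00	0.14
MRGPRX3	198	L	R	Likely deleterious	chr11:18159342	rs28482781	0.02	chr14:53770726	0.07	0.00	0.00
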