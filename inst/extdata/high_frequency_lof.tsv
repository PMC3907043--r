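position	reference	allele_x	allele_y	gene	consequence	n_chinese	x_pct_chinese	y_pct_chinese	n_indian	x_pct_indian	y_pct_indian	n_cynomolgus	x_pct_cynomolgus	y_pct_cynomolgus
chr1:112314147	-	-	g	CELSR2	Frameshift	21	76.2	23.8	35	80.0	20.0	30	65.0	35.0
chr10:90409612	g	g	a	CELSR1	Stop gain	20	70.0	30.0	30	76.7	23.3	29	100.0	0.0
chr1:84773138	a	a	-	LPHN2	Frameshift	20	77.5	22.5	16	84.4	15.6	29	84.5	15.5
chr3:196105681	c	c	t	VIPR2	Stop gain	21	100.0	0.0	33	100.0	0.0	30	76.7	23.3
chr14:53770846	c	c	t	MRGPRX3	Stop gain	21	95.2	4.8	31	82.3	17.7	30	100.0	0.0
chr10:90386626	g	g	a	CELSR1	Stop gain	20	100.0	0.0	26	100.0	0.0	29	77.6	22.4
chr13:124076459	c	c	t	HTR5A	Stop gain	14	100.0	0.0	13	100.0	0.0	20	70.0	30.0
chr1:9594364	c	c	t	TAS1R1	Stop gain	21	100.0	0.0	33	100.0	0.0	29	84.5	15.5
chr10:90412270	g	g	a	CELSR1	Stop gain	21	100.0	0.0	30	100.0	0.0	29	84.5	15.5
chr3:95248643	c	c	t	GHRHR	Stop gain	17	79.4	20.6	21	100.0	0.0	28	100.0	0.0
chr10:90411842	g	g	a	CELSR1	Stop gain	21	85.7	14.3	28	98.2	1.8	29	100.0	0.0
chr10:90385309	g	g	a	CELSR1	Stop gain	20	85.0	15.0	24	100.0	0.0	29	100.0	0.0
chr14:86696825	t	t	-	GRM5	Frameshift	19	97.4	2.6	27	98.1	1.9	28	92.9	7.1
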