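gene	protein_change	rs_number	cosegregation	cadd	polyphen	provean	sift	maf_gnomad
AMOTL1	p.Y605S	NA	I.1 and II.5	26.4	D	D	D	NA
VAV3	p.T124I	rs200980013	I.1 and II.5	23.1	B	N	T	0.00015
CDK5RAP3	p.D271N	rs140552517	I.1 and II.5	22.8	B	D	T	0.00238
ADGRE5	p.R794W	rs369617596	II.5 and III.1	28	D	D	D	0.00013
GLI1	p.R510W	rs149817893	II.5 and III.1	24.4	B	N	D	0.00268
PLXNB2	p.E1804K	rs149124212	II.5	28.1	D	N	D	0.00401
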