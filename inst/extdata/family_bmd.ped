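#family_id	individual_id	father_id	mother_id	sex	affected	z_ls	z_fn
HBMFAM	I.1	0	0	2	2	3.3	2.2
HBMFAM	II.1	0	I.1	1	1	-0.1	1.0
HBMFAM	II.5	0	I.1	2	2	4.6	2.4
HBMFAM	III.1	0	II.5	2	2	1.3	2.2
HBMFAM	III.2	0	II.5	2	1	-0.2	0.7
HBMFAM	III.3	0	II.5	2	1	-0.4	-0.4
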