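#gene	metric (synthetic gnomAD-style missense observed/expected values)
CONSTRG1	1.5
CONSTRG2	1.6
CONSTRG3	1.8
CONSTRG4	2.0
CONSTRG5	1.4
TOLG1	0.8
TOLG2	0.95
TOLG3	1.1
AMOTL1	0.92
VAV3	0.74
CDK5RAP3	0.88
ADGRE5	1.05
GLI1	0.81
PLXNB2	0.9
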