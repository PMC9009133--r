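gene	bmd_gwas	disease	ko_phenotype	function_note
AMOTL1	N	N	N	Motin-family protein; attenuates canonical Wnt/beta-catenin signaling
VAV3	N	N	Vav3 knockout mice display dense bones / high bone mass	Rho-family guanine nucleotide exchange factor; organizes the osteoclast cytoskeleton and stimulates osteoclast activation
CDK5RAP3	Y	N	N	Tumor suppressor (LZAP); inhibits NF-kB signaling and controls nuclear localization of beta-catenin via GSK3
ADGRE5	N	N	Cd97 knockout mouse shows increased trabecular bone volume	Adhesion G protein-coupled receptor (CD97) expressed in osteoclasts; positive regulator of osteoclast differentiation and function
GLI1	N	PA	N	Transcription factor downstream of hedgehog signaling; Indian hedgehog regulates osteoblast differentiation
PLXNB2	Y	N	N	Receptor for semaphorin 4D; promotes osteogenic differentiation through RhoA signaling
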