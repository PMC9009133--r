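---
title: "Family-based rare-variant filtering for a high-BMD pedigree: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Family-based rare-variant filtering for a high-BMD pedigree: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hbmseg)
```

## The problem

High bone mineral density (HBM) sits at the opposite end of the BMD
spectrum from osteoporosis. Families in which HBM segregates as an
apparently autosomal dominant trait are rare and valuable: a gene whose
loss of function raises BMD without secondary pathology is a natural
osteoporosis drug target. The analytical setting, however, is hard: a
single small pedigree (here six members, three affected, three
unaffected), no power for linkage, and whole-exome data in which tens of
thousands of variants are compatible with almost any hypothesis until
aggressively filtered.

This package implements that filtering as an explicit, audited pipeline:
phenotype quantification from DXA Z-scores, a dominant presence/absence
filter, an annotation filter cascade, partitioning of survivors by their
affected carriers, additive two-locus pair detection, and evidence-based
ranking. Because the motivating study's exomes are not publicly
deposited, the package also contains a first-class simulator that
reproduces the study design with planted variants and a truth table, so
every claim the pipeline makes can be verified end to end.

## Phenotype model

BMD Z-scores at lumbar spine (`z_ls`) and femoral neck (`z_fn`) are taken
as given (SD units, age/sex-standardized upstream by the densitometry
software; the package performs no re-standardization). Two operational
HBM definitions are implemented in `bmd_criteria()`:

* **either-site**: `z_ls >= 2.5 | z_fn >= 2.5` (inclusive, per the
  conventional "Z-score of at least +2.5" phrasing);
* **sum-Z**: `z_ls + z_fn > 4` (strict, per "greater than four").

The classification is deliberately *advisory*. In the motivating family,
one affected daughter has sum Z = 3.5 and fails both thresholds, yet was
judged affected given two unambiguous HBM relatives; segregation analysis
must honor that judgment. The pipeline therefore never derives affection
status from Z-scores — `classify_bmd()` output is reported alongside the
input label in `pedigree_report()`, and disagreements stay visible.
Missing Z-scores are an error by default (`on_missing = "error"`): a
missing DXA measurement must never be silently read as 0.

## Variant model and input handling

Variants are one row per decomposed alt allele (VCF 1-based coordinates),
with the annotation fields the cascade consumes: gene, region class,
consequence class, splice flag, population MAF, CADD phred, SIFT-indel
and PROVEAN-indel calls. Parsing is delegated to `vcfR`; decomposition of
multiallelic records, per-alt distribution of `Number=A` INFO values and
GT-to-dosage decoding are pipeline logic. Design choices:

* **Dosage is the primitive** (0/1/2 alt-allele count), not zygosity
  class; what counts as "presence" is decided by the segregation policy.
* **Half-missing genotypes (`./1`) are missing**: a half call certifies
  neither presence nor absence.
* **Absent annotations stay absent** (`NA`), never defaulted. Each filter
  then states explicitly what missingness means (below).
* **Decomposition only, no indel left-alignment.** Normalizing indel
  position requires the reference genome sequence, which this pipeline
  never ingests (annotations are consumed, not computed). Inputs are
  expected to be reference-normalized upstream by the caller's
  variant-calling workflow.

## The filter cascade

Stage order, mirroring the segregation-first protocol:

1. **Dominant presence** — proband carries the variant; no unaffected
   member does. Under the default `segregation_policy()`, presence is any
   non-reference dosage (`any_alt`; a rare homozygote is still a
   carrier — `het_only` is available), and a missing genotype in an
   unaffected member *disqualifies* the variant: absence cannot be
   certified from a no-call. This is conservative and configurable
   because fully genotyped pedigrees make it moot.
2. **Region/consequence** — drop intergenic, UTR, upstream, downstream,
   ncRNA and unknown regions; drop intronic variants without a positive
   splice prediction (an absent splice flag counts as "not predicted to
   affect splicing"); drop synonymous variants.
3. **Frequency** — keep MAF ≤ 0.005 *or MAF absent*. A variant missing
   from the population reference is at most rare; treating absence as
   failure would discard exactly the novel variants the design seeks.
4. **Pathogenicity** — SNVs: CADD phred present and ≥ 20 (an SNV without
   a CADD record cannot demonstrate predicted deleteriousness and is
   dropped). Indels: SIFT-indel damaging **or** PROVEAN-indel deleterious
   by default (`either_damaging`); the stricter conjunctive reading is
   available as `both_damaging` because the underlying protocol sentence
   admits both readings. Indels with neither prediction follow
   `missing_annotation_policy` (default `keep`).
5. **Constraint** — drop variants in genes enriched in missense
   variation per a gnomAD-style table. No published threshold exists for
   "enriched", so the metric (missense o/e, default; or missense Z) and
   cutoff (default o/e > 1.2) are configuration, documented as a user
   decision; genes absent from the table are kept. The packaged table
   (`gene_constraint_synthetic.tsv`) is synthetic.

Stages 2–5 are independent per-variant predicates, so the survivor *set*
is invariant under their permutation (property-tested); only the
per-stage counts in the `FilterTrace` depend on order, which is why the
trace fixes the order above. Trace conservation — input count minus final
output equals the number of dropped ids, no id dropped twice, stage
counts chaining — is asserted on every run.

## Partition and additive pairs

Survivors are partitioned by carrier subset among affected members
(`partition_by_sharing()`); every cell contains the proband by
construction. `additive_pairs()` then enumerates pairs of variants from
distinct non-universal cells whose carrier sets jointly cover all
affected members while neither does alone. With affected set
{proband, mother, daughter}, the only covering configuration is
{proband, mother} × {proband, daughter}: the proband carries both
variants, each other affected member one — and a stronger phenotype in
the double-carrier proband is exactly what an additive two-locus model
predicts. Pairs are restricted to two loci; higher-order covering sets
are out of scope. Output order is fully deterministic (gene, position,
id tie-breaks), and both partition and pairs are validated against naive
brute-force enumeration over hundreds of random instances in the test
suite.

## Evidence-based ranking

The study-style prioritization ("known gene function, animal-model
phenotype, human disease, BMD GWAS association") is formalized as an
explicit gene-evidence table with four categories scored one point each
(`evidence_score`). Equal weighting is a stated convention — the
underlying practice is manual curation with no published weights — and
the shipped `gene_evidence.tsv` encodes the six-candidate worked example
(VAV3 and ADGRE5 each carry knockout bone phenotypes: dense bones and
increased trabecular bone respectively). Ranking is evidence score, then
number of affected carriers, then CADD, then gene/id tie-breaks: a total
order, so shuffled input reproduces byte-identical reports.

## The simulator

`generate_study()` emulates the study design, not sequencing physics:

* **Pedigree**: the six-member, three-affected family (`study_pedigree()`),
  with the unsampled fathers encoded as founders.
* **Planted variants** bypass gene dropping: dosage 1 exactly for the
  intended carriers. Candidates in this design are defined by observed
  carrier subsets, and a proband-only variant is biologically plausible
  via the unsampled paternal side. Decoy annotations are set clearly
  beyond the relevant threshold (e.g. MAF = 1.2 × `maf_max`, CADD = 0.8 ×
  `cadd_min`, both indel predictors neutral) so each decoy's fate is
  unambiguous under either indel rule.
* **Background variants** use standard gene dropping: founder alleles
  Bernoulli(MAF) with MAF log-uniform on [1e-5, 0.5], children sampling
  one allele per parent, no de novo events — Mendelian consistency is
  property-tested over 10,000 transmissions. Annotation distributions
  are field-plausible mixtures (50% coding, 10% indels, CADD uniform on
  [0, 40]); their purpose is to exercise every cascade path, not to match
  an exome's empirical spectrum.
* **Defaults**: the default planted set reproduces the motivating
  design — 38 survivors split 4/11/9/14 over the four sharing cells
  (including one proband+mother and one proband+daughter survivor forming
  the additive pair) plus 25 decoys, five per death stage — with
  `n_background = 0` so the planted cell counts are exact. Background
  variants are switched on where transmission realism matters (their
  cascade fate is then recorded in the truth table rather than chosen).
* **Determinism**: one seed in `simulation_spec()` controls every draw;
  generated files are byte-identical across runs, which the tests assert.
* Synthetic contigs (`S1`–`S3`) and positions avoid real genome
  coordinates so accidental joins against real annotation resources are
  impossible.

What passing tests on synthetic studies do **not** show: robustness to
caller artifacts, coverage gaps, population stratification of MAFs,
annotation disagreement between tools, or pedigrees with loops — real
data properties the generator does not model.

## Numerical and degenerate-input choices

* Threshold comparisons: MAF `<=`, CADD `>=`, either-site `>=`, sum-Z
  strict `>`; boundary values are tested on both sides.
* Empty inputs are valid everywhere (empty VCF, empty survivor set,
  empty evidence table) and produce empty, well-formed outputs.
* Founder MAFs 0 and 1 are allowed in the simulator and produce all-ref /
  all-alt genotypes.
* The analysis path contains no randomness: re-running the pipeline on
  identical inputs is byte-identical.
* Problem sizes used by the test suite: 200 random instances of up to 8
  samples × 64 variants for the brute-force equivalence checks, and
  10,000 transmissions for the Mendelian property — comfortably
  exhaustive for this family size while keeping the suite quick.

## Known limitations

* Only the dominant hypothesis is implemented (no recessive or
  compound-heterozygous models), matching the motivating analysis.
* No statistical cosegregation evidence (LOD scores, Bayes factors) is
  computed; with three affected members the carrier-subset partition *is*
  the evidence summary.
* Unknown-phenotype members are ignored by both the presence filter and
  the sharing partition.
* Annotations are consumed, never computed: the pipeline does not score
  variants (no CADD/SIFT/PROVEAN/VEP) and trusts its input VCF.
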