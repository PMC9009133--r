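#!/usr/bin/env Rscript
# Step 4 — additive two-locus candidate pairs.
#
# With three affected members, no single fully shared variant is required
# to explain the phenotype: two variants at different loci whose carrier
# sets jointly cover all affected members — the proband carrying both,
# each other affected member one — form an additive candidate pair, and
# the proband's more extreme phenotype (sum Z = 7) is consistent with her
# double-carrier status. This step reports the pairs found in the step-3
# study and demonstrates the minimal two-locus configuration, where the
# planted pair is recovered uniquely.

suppressMessages(library(hbmseg))
if (!dir.exists("results/03_pipeline")) stop("run analysis/03_filter_and_partition.R first")

pairs <- read.delim("results/03_pipeline/additive_pairs.tsv",
                    stringsAsFactors = FALSE)
cat("Additive pairs in the full study:", nrow(pairs),
    "(every proband+mother x proband+daughter survivor combination)\n")
if (nrow(pairs) > 0) print(utils::head(pairs[, c("variant_a", "variant_b",
                                                 "pattern_label")], 5))

# minimal configuration: exactly one variant per covering cell
st <- generate_study(simulation_spec(seed = 2024, planted = list(
  planted_variant(c("I.1", "II.5"), "survive", gene = "LOCUS_A"),
  planted_variant(c("II.5", "III.1"), "survive", gene = "LOCUS_B"))),
  "results/04_minimal_study")
res <- run_pipeline(pipeline_config(
  vcf = st$vcf, ped = st$ped, proband_id = "II.5",
  out_dir = "results/04_minimal_pipeline",
  gene_constraint = st$gene_constraint))
cat("Minimal two-locus configuration: ", nrow(res$pairs), " pair (",
    res$pairs$gene_a, " x ", res$pairs$gene_b, "), covering {",
    res$pairs$covered, "}\n", sep = "")
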