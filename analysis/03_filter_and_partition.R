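#!/usr/bin/env Rscript
# Step 3 — dominant-segregation filter cascade and affected-sharing
# partition.
#
# Runs the full pipeline on the synthetic study of step 2: dominant
# presence filter (carried by proband II.5, absent in II.1, III.2, III.3),
# then region/consequence, frequency (MAF <= 0.005), pathogenicity
# (CADD >= 20 for SNVs, SIFT/PROVEAN for indels) and gene-constraint
# filters; survivors are partitioned by which affected members carry them
# and checked variant-by-variant against the simulator's truth table.

suppressMessages(library(hbmseg))
if (!dir.exists("results/02_study")) stop("run analysis/02_simulate_study.R first")

res <- run_pipeline(pipeline_config(
  vcf = "results/02_study/study.vcf", ped = "results/02_study/study.ped",
  proband_id = "II.5", out_dir = "results/03_pipeline",
  gene_constraint = "results/02_study/gene_constraint.tsv",
  gene_evidence = system.file("extdata", "gene_evidence.tsv", package = "hbmseg")))

print(res$trace)
cat("Partition of the", nrow(res$survivors), "survivors:\n")
print(partition_counts(res$partition))

truth <- read.delim("results/02_study/truth.tsv", stringsAsFactors = FALSE)
ok_surv <- setequal(res$survivors$variant_id,
                    truth$variant_id[truth$intended_fate == "survive"])
cell_of <- setNames(truth$intended_cell, truth$variant_id)
ok_cells <- all(vapply(names(res$partition$cells), function(k) {
  all(cell_of[res$partition$cells[[k]]] == k)
}, logical(1)))
cat("Truth-table recovery — survivors:", ok_surv, "| cells:", ok_cells, "\n")
cat("Artifacts under results/03_pipeline/\n")
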