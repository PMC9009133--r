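#' Filter cascade configuration
#'
#' Thresholds and policies for the annotation filter cascade applied after
#' the dominant presence filter. Defaults reproduce the exome-filtering
#' protocol the pipeline models: keep variants with population MAF at most
#' 0.005 (or no frequency record), SNVs with CADD phred at least 20, indels
#' called damaging by SIFT-indel or deleterious by PROVEAN-indel, coding
#' non-synonymous consequences (intronic only when predicted to affect the
#' splice site), and genes not enriched in missense variation.
#'
#' @param maf_max maximum population minor allele frequency retained.
#' @param cadd_min minimum CADD phred score retained for SNVs.
#' @param excluded_region_classes region classes removed outright.
#' @param exclude_synonymous drop synonymous coding variants.
#' @param intronic_requires_splice_flag drop intronic variants not flagged
#'   as splice-affecting.
#' @param indel_rule `"either_damaging"` keeps an indel when either
#'   predictor calls damage; `"both_damaging"` requires both.
#' @param constraint_metric `"missense_oe"` (enriched = observed/expected
#'   above threshold) or `"missense_z"` (enriched = Z below threshold).
#' @param constraint_threshold cutoff for the constraint metric.
#' @param missing_annotation_policy `"keep"` (default) or `"drop"` for
#'   indels with no SIFT/PROVEAN prediction. Missing MAF is always kept: a
#'   variant absent from the population reference is at most rare, and
#'   missing data must not silently discard candidates.
#' @return A `filter_config` list.
#' @export
filter_config <- function(maf_max = 0.005,
                          cadd_min = 20,
                          excluded_region_classes = c("intergenic", "utr5", "utr3",
                                                      "upstream", "downstream",
                                                      "ncRNA", "unknown"),
                          exclude_synonymous = TRUE,
                          intronic_requires_splice_flag = TRUE,
                          indel_rule = c("either_damaging", "both_damaging"),
                          constraint_metric = c("missense_oe", "missense_z"),
                          constraint_threshold = 1.2,
                          missing_annotation_policy = c("keep", "drop")) {
  indel_rule <- match.arg(indel_rule)
  constraint_metric <- match.arg(constraint_metric)
  missing_annotation_policy <- match.arg(missing_annotation_policy)
  stopifnot(maf_max > 0, maf_max <= 1, cadd_min >= 0,
            is.finite(constraint_threshold))
  bad <- setdiff(excluded_region_classes, .REGION_LEVELS)
  if (length(bad) > 0L) stop("unknown region class(es): ", paste(bad, collapse = ", "))
  structure(list(maf_max = maf_max, cadd_min = cadd_min,
                 excluded_region_classes = excluded_region_classes,
                 exclude_synonymous = exclude_synonymous,
                 intronic_requires_splice_flag = intronic_requires_splice_flag,
                 indel_rule = indel_rule,
                 constraint_metric = constraint_metric,
                 constraint_threshold = constraint_threshold,
                 missing_annotation_policy = missing_annotation_policy),
            class = "filter_config")
}

#' Region and consequence filter
#'
#' Drops variants outside the coding region (intergenic, UTRs, upstream,
#' downstream, ncRNA, unknown), intronic variants not predicted to affect
#' the splice site, and synonymous variants. A missing splice flag counts
#' as "not predicted to affect splicing": the exclusion targets intronic
#' variants lacking a positive splice prediction.
#'
#' @param variants an [annotated_variants()] table (or any data frame with
#'   `region_class`, `consequence_class`, `splice_affecting`).
#' @param cfg a [filter_config()].
#' @return Logical keep vector, one entry per variant. Total function: no
#'   annotation combination errors.
#' @export
region_consequence_filter <- function(variants, cfg = filter_config()) {
  region <- variants$region_class
  csq <- variants$consequence_class
  splice <- !is.na(variants$splice_affecting) & variants$splice_affecting
  keep <- !(region %in% cfg$excluded_region_classes)
  if (cfg$intronic_requires_splice_flag) {
    keep <- keep & !(region == "intronic" & !splice)
  }
  if (cfg$exclude_synonymous) {
    keep <- keep & !(!is.na(csq) & csq == "synonymous")
  }
  keep
}

#' Population frequency filter
#'
#' Keeps variants whose population minor allele frequency is at most
#' `maf_max`, and variants with no frequency record (absence from the
#' population reference is evidence of rarity, not of commonness).
#'
#' @inheritParams region_consequence_filter
#' @return Logical keep vector.
#' @export
frequency_filter <- function(variants, cfg = filter_config()) {
  is.na(variants$maf) | variants$maf <= cfg$maf_max
}

#' Pathogenicity filter
#'
#' SNVs are kept when their CADD phred score is present and at least
#' `cadd_min`. Indels are kept when SIFT-indel calls them damaging or
#' PROVEAN-indel calls them deleterious (`indel_rule = "either_damaging"`,
#' the default) or only when both do (`"both_damaging"`); an indel with
#' neither prediction available follows `missing_annotation_policy`.
#'
#' @inheritParams region_consequence_filter
#' @return Logical keep vector.
#' @export
pathogenicity_filter <- function(variants, cfg = filter_config()) {
  is_snv <- variants$variant_class == "snv"
  keep_snv <- !is.na(variants$cadd_phred) & variants$cadd_phred >= cfg$cadd_min

  sift_dmg <- !is.na(variants$sift_indel) & variants$sift_indel == "damaging"
  prov_dmg <- !is.na(variants$provean_indel) & variants$provean_indel == "deleterious"
  no_pred <- is.na(variants$sift_indel) & is.na(variants$provean_indel)
  keep_indel <- if (cfg$indel_rule == "either_damaging") sift_dmg | prov_dmg
                else sift_dmg & prov_dmg
  if (cfg$missing_annotation_policy == "keep") {
    keep_indel <- keep_indel | no_pred
  }
  ifelse(is_snv, keep_snv, keep_indel)
}

#' Gene-level missense constraint filter
#'
#' Drops variants in genes enriched in missense variation according to a
#' gnomAD-style constraint table: under `missense_oe`, enriched means
#' observed/expected above `constraint_threshold`; under `missense_z`,
#' enriched means a Z-score below it. Genes absent from the table are kept.
#'
#' @inheritParams region_consequence_filter
#' @param gene_constraint named numeric vector (gene -> metric value), e.g.
#'   from [read_gene_constraint()], or `NULL` to keep everything.
#' @return Logical keep vector.
#' @export
constraint_filter <- function(variants, gene_constraint, cfg = filter_config()) {
  if (is.null(gene_constraint) || length(gene_constraint) == 0L) {
    return(rep(TRUE, nrow(variants)))
  }
  metric <- unname(gene_constraint[variants$gene])
  enriched <- if (cfg$constraint_metric == "missense_oe") {
    !is.na(metric) & metric > cfg$constraint_threshold
  } else {
    !is.na(metric) & metric < cfg$constraint_threshold
  }
  !enriched
}

#' Read a gene constraint table
#'
#' Two-column TSV (gene, metric value); `#`-prefixed lines are comments.
#'
#' @param path path to the TSV.
#' @return Named numeric vector, gene -> metric.
#' @export
read_gene_constraint <- function(path) {
  if (!file.exists(path)) stop("gene constraint table not found: ", path)
  tab <- read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                    col.names = c("gene", "metric"),
                    colClasses = c("character", "numeric"))
  if (anyDuplicated(tab$gene)) {
    stop("duplicate gene in constraint table: ",
         paste(unique(tab$gene[duplicated(tab$gene)]), collapse = ", "))
  }
  stats::setNames(tab$metric, tab$gene)
}

.new_trace <- function() {
  structure(list(stage = character(), n_in = integer(), n_out = integer(),
                 dropped = list()), class = "filter_trace")
}

.trace_add <- function(trace, stage, n_in, n_out, dropped) {
  trace$stage <- c(trace$stage, stage)
  trace$n_in <- c(trace$n_in, n_in)
  trace$n_out <- c(trace$n_out, n_out)
  trace$dropped <- c(trace$dropped, list(dropped))
  trace
}

#' @export
print.filter_trace <- function(x, ...) {
  cat("filter_trace:\n")
  for (i in seq_along(x$stage)) {
    cat(sprintf("  %-20s %4d -> %4d  (-%d)\n", x$stage[i], x$n_in[i],
                x$n_out[i], x$n_in[i] - x$n_out[i]))
  }
  invisible(x)
}

#' @export
as.data.frame.filter_trace <- function(x, ...) {
  data.frame(stage = x$stage, n_in = x$n_in, n_out = x$n_out,
             n_dropped = x$n_in - x$n_out, stringsAsFactors = FALSE)
}

#' Run the full variant filter cascade
#'
#' Applies, in order: the dominant presence filter (proband carries the
#' variant, no unaffected member does), the region/consequence filter, the
#' population frequency filter, the pathogenicity filter, and the gene
#' constraint filter. The four annotation filters are independent
#' per-variant predicates, so the surviving set does not depend on their
#' order — only the per-stage counts in the trace do. The trace records
#' each stage's input/output counts and the ids it dropped; conservation
#' (`n_in` of the first stage minus final `n_out` equals the total number
#' of dropped ids, no id dropped twice) is asserted on every run.
#'
#' @param variants an [annotated_variants()] table.
#' @param genotypes dosage matrix (variants x samples), rownames =
#'   `variant_id`.
#' @param ped an `hbm_pedigree`; sample columns must cover the proband and
#'   all unaffected members.
#' @param cfg a [filter_config()].
#' @param policy a [segregation_policy()].
#' @param gene_constraint named numeric vector for [constraint_filter()],
#'   or `NULL` to skip constraint filtering.
#' @return List with `survivors` (subset of `variants`) and `trace` (a
#'   `filter_trace`).
#' @export
run_cascade <- function(variants, genotypes, ped, cfg = filter_config(),
                        policy = segregation_policy(), gene_constraint = NULL) {
  stopifnot(inherits(ped, "hbm_pedigree"))
  if (nrow(variants) != nrow(genotypes)) {
    stop("variants and genotypes disagree on variant count")
  }
  trace <- .new_trace()
  keep <- rep(TRUE, nrow(variants))

  apply_stage <- function(stage, keep_stage) {
    n_in <- sum(keep)
    dropped <- variants$variant_id[keep & !keep_stage]
    keep <<- keep & keep_stage
    trace <<- .trace_add(trace, stage, n_in, sum(keep), dropped)
  }

  apply_stage("dominant_presence",
              dominant_presence(variants$variant_id, genotypes, ped, policy))
  apply_stage("region_consequence", region_consequence_filter(variants, cfg))
  apply_stage("frequency", frequency_filter(variants, cfg))
  apply_stage("pathogenicity", pathogenicity_filter(variants, cfg))
  apply_stage("constraint", constraint_filter(variants, gene_constraint, cfg))

  all_dropped <- unlist(trace$dropped)
  stopifnot(length(all_dropped) == trace$n_in[1] - trace$n_out[length(trace$n_out)],
            !anyDuplicated(all_dropped),
            all(trace$n_out <= trace$n_in),
            all(trace$n_in[-1] == trace$n_out[-length(trace$n_out)]))
  survivors <- variants[keep, , drop = FALSE]
  rownames(survivors) <- NULL
  class(survivors) <- class(variants)
  list(survivors = survivors, trace = trace)
}
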