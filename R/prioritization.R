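#' Load a gene-level functional evidence table
#'
#' Tab-separated table with a header and columns `gene`, `bmd_gwas`
#' (`Y`/`N`: gene associated with BMD in genome-wide association studies),
#' `disease` (OMIM-style disease note, `N` for none), `ko_phenotype`
#' (knockout/animal-model bone phenotype, `N` for none) and
#' `function_note` (known function relevant to bone biology, `N` for
#' none). This packages, as an explicit table, the public-database lookup
#' (GWAS catalogs, OMIM, model-organism databases, literature) that
#' candidate-gene prioritization otherwise performs by hand.
#'
#' @param path path to the TSV.
#' @return Named list of `gene_evidence` records, each carrying an
#'   `evidence_score` equal to its number of positive evidence categories.
#' @export
load_gene_evidence <- function(path) {
  if (!file.exists(path)) stop("gene evidence table not found: ", path)
  tab <- read.table(path, sep = "\t", header = TRUE, comment.char = "",
                    quote = "", stringsAsFactors = FALSE)
  req <- c("gene", "bmd_gwas", "disease", "ko_phenotype", "function_note")
  missing_cols <- setdiff(req, names(tab))
  if (length(missing_cols) > 0L) {
    stop("gene evidence table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (nrow(tab) == 0L) return(stats::setNames(list(), character(0)))
  if (any(!tab$bmd_gwas %in% c("Y", "N"))) {
    stop("bmd_gwas must be Y or N")
  }
  if (anyDuplicated(tab$gene)) {
    stop("duplicate gene in evidence table: ",
         paste(unique(tab$gene[duplicated(tab$gene)]), collapse = ", "))
  }
  records <- lapply(seq_len(nrow(tab)), function(i) {
    rec <- as.list(tab[i, req])
    rec$evidence_score <- evidence_score(rec)
    structure(rec, class = "gene_evidence")
  })
  stats::setNames(records, tab$gene)
}

#' Count positive evidence categories for a gene
#'
#' One point for each of: BMD GWAS association (`bmd_gwas == "Y"`), a human
#' disease annotation, a knockout/animal-model phenotype, and a relevant
#' known function. `"N"`, the empty string and `NA` are negative. Equal
#' weighting across categories is a stated convention of this package's
#' formalization of evidence-based ranking, not an empirical calibration.
#'
#' @param ev a `gene_evidence` record (or a list with the evidence fields).
#' @return Integer in 0..4.
#' @export
evidence_score <- function(ev) {
  positive <- function(x) !is.na(x) && nzchar(x) && x != "N"
  sum(ev$bmd_gwas %in% "Y", positive(ev$disease), positive(ev$ko_phenotype),
      positive(ev$function_note))
}

#' Annotate surviving variants with evidence and rank them
#'
#' Joins each surviving variant with its affected-sharing cell label and
#' its gene's functional evidence (genes without an evidence entry score
#' 0), then ranks by evidence score (descending), cell size — the number
#' of affected carriers (descending), CADD phred (descending), breaking
#' remaining ties by gene name and variant id so the order is total and
#' re-running on shuffled input yields an identical report.
#'
#' @param survivors an [annotated_variants()] table of cascade survivors.
#' @param partition the `hbm_partition` of those survivors.
#' @param evidence mapping from [load_gene_evidence()] (may be empty).
#' @return Data frame: survivor columns plus `cosegregation` (cell label),
#'   `n_affected_carriers`, evidence columns, `evidence_score` and `rank`.
#' @export
annotate_and_rank <- function(survivors, partition, evidence = list()) {
  stopifnot(inherits(partition, "hbm_partition"))
  if (nrow(survivors) == 0L) {
    out <- as.data.frame(survivors)
    out$cosegregation <- character(0)
    out$n_affected_carriers <- integer(0)
    out$bmd_gwas <- character(0)
    out$disease <- character(0)
    out$ko_phenotype <- character(0)
    out$function_note <- character(0)
    out$evidence_score <- integer(0)
    out$rank <- integer(0)
    return(out)
  }
  cell_of <- rep(NA_character_, nrow(survivors))
  for (key in names(partition$cells)) {
    cell_of[survivors$variant_id %in% partition$cells[[key]]] <- key
  }
  if (any(is.na(cell_of))) {
    stop("survivor(s) missing from partition: ",
         paste(survivors$variant_id[is.na(cell_of)], collapse = ", "))
  }
  ev_field <- function(gene, field, default) {
    rec <- evidence[[gene]]
    if (is.null(rec)) default else rec[[field]]
  }
  out <- as.data.frame(survivors)
  out$cosegregation <- cell_of
  out$n_affected_carriers <- lengths(strsplit(cell_of, ",", fixed = TRUE))
  out$bmd_gwas <- vapply(out$gene, ev_field, character(1),
                         field = "bmd_gwas", default = "N")
  out$disease <- vapply(out$gene, ev_field, character(1),
                        field = "disease", default = "N")
  out$ko_phenotype <- vapply(out$gene, ev_field, character(1),
                             field = "ko_phenotype", default = "N")
  out$function_note <- vapply(out$gene, ev_field, character(1),
                              field = "function_note", default = "N")
  out$evidence_score <- vapply(out$gene, function(g) {
    rec <- evidence[[g]]
    if (is.null(rec)) 0L else as.integer(rec$evidence_score)
  }, integer(1))
  ord <- order(-out$evidence_score, -out$n_affected_carriers,
               -ifelse(is.na(out$cadd_phred), -Inf, out$cadd_phred),
               out$gene, out$variant_id)
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
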