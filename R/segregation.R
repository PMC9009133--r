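#' Segregation policy
#'
#' How genotype dosages translate into "carries the variant" and how
#' missing genotypes are handled by the dominant presence filter. Under a
#' rare dominant model heterozygous carriers are the expectation, but the
#' default counts any non-reference dosage as presence (`any_alt`), since
#' a rare homozygote is still a carrier. A missing genotype in an
#' unaffected member disqualifies the variant by default: absence cannot be
#' certified from a no-call.
#'
#' @param presence_rule `"any_alt"` (dosage 1 or 2) or `"het_only"`
#'   (dosage exactly 1).
#' @param missing_in_unaffected `"disqualify"` (default) or
#'   `"treat_absent"` for an unaffected member with a missing genotype.
#' @param missing_in_affected `"treat_absent"` (default) or
#'   `"treat_present_unknown"` (count the member as a carrier) for an
#'   affected member with a missing genotype.
#' @return A `segregation_policy` list.
#' @export
segregation_policy <- function(presence_rule = c("any_alt", "het_only"),
                               missing_in_unaffected = c("disqualify", "treat_absent"),
                               missing_in_affected = c("treat_absent",
                                                       "treat_present_unknown")) {
  structure(list(presence_rule = match.arg(presence_rule),
                 missing_in_unaffected = match.arg(missing_in_unaffected),
                 missing_in_affected = match.arg(missing_in_affected)),
            class = "segregation_policy")
}

# Presence indicator per sample for one dosage vector; NA handled by caller.
.presence <- function(dosage, policy) {
  if (policy$presence_rule == "any_alt") !is.na(dosage) & dosage >= 1L
  else !is.na(dosage) & dosage == 1L
}

#' Carrier set of a variant
#'
#' Samples whose dosage satisfies the presence rule. Affected members with
#' a missing genotype are added under
#' `missing_in_affected = "treat_present_unknown"` when a pedigree is
#' supplied; otherwise missing genotypes never contribute carriers.
#'
#' @param variant_id id of the variant (a rowname of `genotypes`).
#' @param genotypes dosage matrix (variants x samples).
#' @param policy a [segregation_policy()].
#' @param ped optionally, an `hbm_pedigree` (needed only for the
#'   `treat_present_unknown` policy).
#' @return Character vector of sample ids.
#' @export
carrier_set <- function(variant_id, genotypes, policy = segregation_policy(),
                        ped = NULL) {
  if (!variant_id %in% rownames(genotypes)) {
    stop("unknown variant id: ", variant_id)
  }
  dosage <- genotypes[variant_id, ]
  carriers <- colnames(genotypes)[.presence(dosage, policy)]
  if (!is.null(ped) && policy$missing_in_affected == "treat_present_unknown") {
    miss_aff <- intersect(colnames(genotypes)[is.na(dosage)], affected_ids(ped))
    carriers <- union(carriers, miss_aff)
  }
  sort(carriers)
}

#' Dominant presence filter
#'
#' The anchoring filter of the dominant-segregation hypothesis: keep a
#' variant iff the proband carries it and no unaffected member does.
#' Members labelled `unknown` are ignored. A missing genotype in an
#' unaffected member disqualifies or is treated as absent per the policy;
#' a missing proband genotype always fails (presence cannot be certified).
#'
#' @param variant_ids character vector of variant ids (rownames of
#'   `genotypes`).
#' @param genotypes dosage matrix (variants x samples).
#' @param ped an `hbm_pedigree`.
#' @param policy a [segregation_policy()].
#' @return Logical vector, one entry per variant id.
#' @export
dominant_presence <- function(variant_ids, genotypes, ped,
                              policy = segregation_policy()) {
  stopifnot(inherits(ped, "hbm_pedigree"))
  pro <- proband_id(ped)
  unaff <- unaffected_ids(ped)
  missing_samples <- setdiff(c(pro, unaff), colnames(genotypes))
  if (length(missing_samples) > 0L) {
    stop("genotype matrix lacks sample(s): ", paste(missing_samples, collapse = ", "))
  }
  vapply(variant_ids, function(vid) {
    if (!vid %in% rownames(genotypes)) stop("unknown variant id: ", vid)
    dosage <- genotypes[vid, ]
    if (!.presence(dosage[pro], policy)) return(FALSE)
    d_un <- dosage[unaff]
    if (any(.presence(d_un, policy))) return(FALSE)
    if (policy$missing_in_unaffected == "disqualify" && any(is.na(d_un))) {
      return(FALSE)
    }
    TRUE
  }, logical(1), USE.NAMES = FALSE)
}

.cell_key <- function(ids) paste(sort(ids), collapse = ",")

#' Partition survivors by affected-carrier subset
#'
#' Assigns each surviving variant to the cell keyed by the subset of
#' affected individuals carrying it (always containing the proband, by
#' construction of the presence filter). With three affected members
#' including the proband there are exactly four possible cells: all three,
#' proband + each other affected, and proband only.
#'
#' @param survivor_ids variant ids that passed [dominant_presence()].
#' @param genotypes dosage matrix (variants x samples).
#' @param ped an `hbm_pedigree`.
#' @param policy a [segregation_policy()].
#' @return An `hbm_partition`: list with `cells` (named list, cell key =
#'   sorted comma-joined affected ids -> variant ids), `universe`,
#'   `affected`, `proband`. Cells are pairwise disjoint and exhaust the
#'   universe (asserted).
#' @export
partition_by_sharing <- function(survivor_ids, genotypes, ped,
                                 policy = segregation_policy()) {
  stopifnot(inherits(ped, "hbm_pedigree"))
  aff <- sort(affected_ids(ped))
  pro <- proband_id(ped)
  cells <- list()
  for (vid in survivor_ids) {
    carriers <- intersect(carrier_set(vid, genotypes, policy, ped), aff)
    if (!pro %in% carriers) {
      stop("internal consistency error: survivor ", vid,
           " has a carrier set lacking the proband")
    }
    key <- .cell_key(carriers)
    cells[[key]] <- c(cells[[key]], vid)
  }
  stopifnot(sum(lengths(cells)) == length(survivor_ids),
            !anyDuplicated(unlist(cells)))
  structure(list(cells = cells, universe = as.character(survivor_ids),
                 affected = aff, proband = pro),
            class = "hbm_partition")
}

#' @export
print.hbm_partition <- function(x, ...) {
  cat(sprintf("hbm_partition: %d variants over %d cell(s); affected = {%s}\n",
              length(x$universe), length(x$cells),
              paste(x$affected, collapse = ", ")))
  for (key in names(x$cells)) {
    cat(sprintf("  {%s}: %d variant(s)\n", key, length(x$cells[[key]])))
  }
  invisible(x)
}

#' Cell counts of a sharing partition
#'
#' @param partition an `hbm_partition`.
#' @return Named integer vector, cell key -> number of variants.
#' @export
partition_counts <- function(partition) {
  stopifnot(inherits(partition, "hbm_partition"))
  vapply(partition$cells, length, integer(1))
}

#' Detect additive two-locus candidate pairs
#'
#' An additive pair is two variants from distinct, non-universal partition
#' cells whose affected-carrier sets jointly cover every affected member
#' while neither does alone — the configuration in which the proband
#' carries both variants and each remaining affected member carries one,
#' so two loci together could explain the family's phenotype and the
#' proband's more extreme value. Output order is deterministic: pair
#' members and rows sort by (gene, chrom, position, id) when variant
#' annotations are supplied, else by id.
#'
#' @param partition an `hbm_partition` from [partition_by_sharing()].
#' @param ped an `hbm_pedigree`.
#' @param variants optionally, the [annotated_variants()] table supplying
#'   gene/position sort keys and gene labels.
#' @return Data frame with one row per pair: `variant_a`, `variant_b`,
#'   `gene_a`, `gene_b`, `carriers_a`, `carriers_b`, `covered`,
#'   `pattern_label`. Zero rows when no pair covers the affected set.
#' @export
additive_pairs <- function(partition, ped, variants = NULL) {
  stopifnot(inherits(partition, "hbm_partition"), inherits(ped, "hbm_pedigree"))
  aff <- sort(affected_ids(ped))
  full_key <- .cell_key(aff)
  keys <- setdiff(names(partition$cells), full_key)

  sort_key <- function(vid) {
    if (is.null(variants)) return(vid)
    i <- match(vid, variants$variant_id)
    sprintf("%s|%s|%012d|%s",
            ifelse(is.na(i), "~", variants$gene[i]),
            ifelse(is.na(i), "~", variants$chrom[i]),
            ifelse(is.na(i), 0L, variants$pos[i]), vid)
  }
  gene_of <- function(vid) {
    if (is.null(variants)) return(NA_character_)
    variants$gene[match(vid, variants$variant_id)]
  }

  rows <- list()
  if (length(keys) >= 2L) {
    for (i in seq_len(length(keys) - 1L)) {
      for (j in seq(i + 1L, length(keys))) {
        set_i <- strsplit(keys[i], ",", fixed = TRUE)[[1]]
        set_j <- strsplit(keys[j], ",", fixed = TRUE)[[1]]
        if (!setequal(union(set_i, set_j), aff)) next
        for (va in partition$cells[[keys[i]]]) {
          for (vb in partition$cells[[keys[j]]]) {
            ordered <- order(c(sort_key(va), sort_key(vb)))
            pair <- c(va, vb)[ordered]
            carr <- list(set_i, set_j)[ordered]
            rows[[length(rows) + 1L]] <- data.frame(
              variant_a = pair[1], variant_b = pair[2],
              gene_a = gene_of(pair[1]), gene_b = gene_of(pair[2]),
              carriers_a = .cell_key(carr[[1]]), carriers_b = .cell_key(carr[[2]]),
              covered = .cell_key(aff),
              pattern_label = paste(.cell_key(carr[[1]]), "|", .cell_key(carr[[2]])),
              stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  out <- if (length(rows) == 0L) {
    data.frame(variant_a = character(), variant_b = character(),
               gene_a = character(), gene_b = character(),
               carriers_a = character(), carriers_b = character(),
               covered = character(), pattern_label = character(),
               stringsAsFactors = FALSE)
  } else {
    do.call(rbind, rows)
  }
  out <- out[order(sort_key(out$variant_a), sort_key(out$variant_b)), , drop = FALSE]
  rownames(out) <- NULL
  out
}
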