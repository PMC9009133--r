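#' High bone mass classification criteria
#'
#' Two operational thresholds are in clinical use for the high bone mass
#' (HBM) phenotype measured by DXA: a Z-score of at least +2.5 at either the
#' lumbar spine (LS) or the femoral neck (FN), or a sum of the LS and FN
#' Z-scores strictly greater than 4. The comparison directions differ on
#' purpose: the either-site rule is inclusive (`>=`), the sum rule strict
#' (`>`).
#'
#' @param mode `"either_site"` or `"sum_z"`.
#' @param either_site_threshold Z-score threshold applied per site
#'   (SD units; default +2.5).
#' @param sum_threshold threshold on `z_ls + z_fn` (SD units; default 4,
#'   compared with strict `>`).
#' @return A `bmd_criteria` list.
#' @export
bmd_criteria <- function(mode = c("either_site", "sum_z"),
                         either_site_threshold = 2.5,
                         sum_threshold = 4.0) {
  mode <- match.arg(mode)
  stopifnot(is.finite(either_site_threshold), is.finite(sum_threshold))
  structure(list(mode = mode,
                 either_site_threshold = either_site_threshold,
                 sum_threshold = sum_threshold),
            class = "bmd_criteria")
}

#' Sum of lumbar-spine and femoral-neck BMD Z-scores
#'
#' The family-level phenotype summary: `z_ls + z_fn`. Missing values are an
#' error, never silently treated as zero — a missing DXA measurement must
#' not masquerade as an average one.
#'
#' @param z_ls,z_fn numeric vectors of Z-scores (SD units), recycled to a
#'   common length.
#' @return Numeric vector of sums.
#' @examples
#' sum_z(4.6, 2.4)  # 7
#' @export
sum_z <- function(z_ls, z_fn) {
  if (any(is.na(z_ls)) || any(is.na(z_fn))) {
    stop("sum_z: missing Z-score (z_ls or z_fn is NA); ",
         "refusing to treat missing data as 0")
  }
  z_ls + z_fn
}

#' Advisory HBM classification from BMD Z-scores
#'
#' Applies a [bmd_criteria()] rule to Z-scores and returns `"hbm"` or
#' `"normal"`. This is advisory only: the pipeline's segregation machinery
#' always uses the input affection labels of the pedigree, because the
#' clinical call may incorporate context the thresholds do not capture
#' (an individual near the threshold in a family segregating the trait may
#' legitimately be labelled affected).
#'
#' @param z_ls,z_fn numeric vectors of Z-scores (SD units).
#' @param criteria a [bmd_criteria()] object.
#' @param on_missing `"error"` (default) to reject missing Z-scores needed
#'   by the chosen mode, `"na"` to return `NA` for those entries.
#' @return Character vector in `c("hbm", "normal")` (possibly `NA` under
#'   `on_missing = "na"`).
#' @examples
#' classify_bmd(4.6, 2.4, bmd_criteria("either_site"))  # "hbm"
#' classify_bmd(1.3, 2.2, bmd_criteria("sum_z"))        # "normal": 3.5 <= 4
#' @export
classify_bmd <- function(z_ls, z_fn, criteria = bmd_criteria(),
                         on_missing = c("error", "na")) {
  stopifnot(inherits(criteria, "bmd_criteria"))
  on_missing <- match.arg(on_missing)
  n <- max(length(z_ls), length(z_fn))
  z_ls <- rep_len(as.numeric(z_ls), n)
  z_fn <- rep_len(as.numeric(z_fn), n)
  miss <- is.na(z_ls) | is.na(z_fn)
  if (any(miss) && on_missing == "error") {
    stop("classify_bmd: missing Z-score(s); use on_missing = \"na\" to ",
         "propagate NA instead")
  }
  hbm <- if (criteria$mode == "either_site") {
    z_ls >= criteria$either_site_threshold | z_fn >= criteria$either_site_threshold
  } else {
    (z_ls + z_fn) > criteria$sum_threshold
  }
  out <- ifelse(hbm, "hbm", "normal")
  out[miss] <- NA_character_
  out
}

#' Pedigree phenotype report
#'
#' Echoes the pedigree with the derived sum Z-score and the advisory HBM
#' classification under the supplied criteria, alongside the authoritative
#' input affection label, so disagreements between the label and the
#' threshold rule are visible rather than silently resolved.
#'
#' @param ped an `hbm_pedigree`.
#' @param criteria a [bmd_criteria()] object.
#' @return Data frame with columns of `ped` plus `sum_z` and
#'   `bmd_advisory`.
#' @export
pedigree_report <- function(ped, criteria = bmd_criteria()) {
  stopifnot(inherits(ped, "hbm_pedigree"))
  out <- as.data.frame(ped)
  has_both <- !is.na(ped$z_ls) & !is.na(ped$z_fn)
  out$sum_z <- NA_real_
  out$sum_z[has_both] <- ped$z_ls[has_both] + ped$z_fn[has_both]
  out$bmd_advisory <- classify_bmd(ped$z_ls, ped$z_fn, criteria, on_missing = "na")
  out
}
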