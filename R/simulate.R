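#' @importFrom stats rbinom runif setNames
NULL

#' The six-member study pedigree
#'
#' The family structure the synthetic generator emulates: a proband
#' ascertained for an extreme BMD (sum Z-score 7), her mother and one
#' daughter also with high BMD, and a brother and two daughters with
#' normal BMD — three affected and three unaffected members in total, with
#' the fathers of both sibships unsampled (founder marker). Z-scores are
#' the family's DXA values at lumbar spine and femoral neck.
#'
#' @return An `hbm_pedigree` with proband `II.5`.
#' @export
study_pedigree <- function() {
  pedigree(data.frame(
    family_id = "HBMFAM",
    individual_id = c("I.1", "II.1", "II.5", "III.1", "III.2", "III.3"),
    father_id = c("0", "0", "0", "0", "0", "0"),
    mother_id = c("0", "I.1", "I.1", "II.5", "II.5", "II.5"),
    sex = c("female", "male", "female", "female", "female", "female"),
    affected = c("affected", "unaffected", "affected", "affected",
                 "unaffected", "unaffected"),
    z_ls = c(3.3, -0.1, 4.6, 1.3, -0.2, -0.4),
    z_fn = c(2.2, 1.0, 2.4, 2.2, 0.7, -0.4),
    stringsAsFactors = FALSE
  ), proband_id = "II.5")
}

#' Gene-dropping genotype simulation
#'
#' Simulates biallelic genotypes down a pedigree: each founder-side allele
#' is drawn Bernoulli(`founder_maf`), and each non-founder receives one
#' allele sampled uniformly from each parent's two alleles (a parent coded
#' with the founder marker `"0"` contributes a population draw). There is
#' no de novo mutation: a child allele always traces to a parent or to a
#' founder draw.
#'
#' `simulate_genotype_matrix()` simulates one variant per entry of
#' `founder_mafs`; `simulate_genotypes()` is the single-variant case.
#'
#' @param ped an `hbm_pedigree`.
#' @param founder_mafs numeric vector of founder allele frequencies in
#'   `[0, 1]`, one per variant.
#' @param founder_maf a single founder allele frequency.
#' @param seed optional integer seed; when given, output is reproducible.
#' @return `simulate_genotype_matrix()`: integer dosage matrix (variants x
#'   samples). `simulate_genotypes()`: named integer dosage vector.
#' @export
simulate_genotype_matrix <- function(ped, founder_mafs, seed = NULL) {
  stopifnot(inherits(ped, "hbm_pedigree"))
  if (any(founder_mafs < 0 | founder_mafs > 1 | is.na(founder_mafs))) {
    stop("founder_mafs must lie in [0, 1]")
  }
  if (!is.null(seed)) set.seed(seed)
  n <- length(founder_mafs)
  ids <- ped$individual_id
  a_pat <- a_mat <- matrix(NA_integer_, nrow = length(ids), ncol = n,
                           dimnames = list(ids, NULL))
  for (id in .topological_order(ped)) {
    row <- ped[ped$individual_id == id, ]
    draw_side <- function(parent) {
      if (parent == PED_FOUNDER) {
        rbinom(n, 1L, founder_mafs)
      } else {
        pick <- rbinom(n, 1L, 0.5)
        ifelse(pick == 1L, a_pat[parent, ], a_mat[parent, ])
      }
    }
    a_pat[id, ] <- draw_side(row$father_id)
    a_mat[id, ] <- draw_side(row$mother_id)
  }
  t(a_pat + a_mat)
}

#' @rdname simulate_genotype_matrix
#' @export
simulate_genotypes <- function(ped, founder_maf, seed = NULL) {
  m <- simulate_genotype_matrix(ped, founder_maf, seed = seed)
  setNames(as.integer(m[1, ]), colnames(m))
}

#' Count Mendelian violations in a genotype matrix
#'
#' For every (child, variant) pair where a parent is in the pedigree and
#' genotyped, checks the unphased-dosage transmission rules: a child
#' dosage of 2 requires each known parent to carry the allele, a dosage of
#' 1 requires some parent to carry it (and is impossible if both parents
#' are homozygous alt), and a dosage of 0 forbids a homozygous-alt parent.
#' With one known parent only that parent's obligations are checked.
#'
#' @param genotypes dosage matrix (variants x samples).
#' @param ped an `hbm_pedigree`; only members present as columns are
#'   checked.
#' @return Integer count of violating (child, variant) pairs.
#' @export
mendelian_violations <- function(genotypes, ped) {
  stopifnot(inherits(ped, "hbm_pedigree"))
  total <- 0L
  for (i in seq_len(nrow(ped))) {
    id <- ped$individual_id[i]
    f <- ped$father_id[i]
    m <- ped$mother_id[i]
    if (!id %in% colnames(genotypes)) next
    dc <- genotypes[, id]
    have_f <- f != PED_FOUNDER && f %in% colnames(genotypes)
    have_m <- m != PED_FOUNDER && m %in% colnames(genotypes)
    if (have_f && have_m) {
      df <- genotypes[, f]; dm <- genotypes[, m]
      bad <- (dc == 2L & (df == 0L | dm == 0L)) |
        (dc == 1L & df == 0L & dm == 0L) |
        (dc == 1L & df == 2L & dm == 2L) |
        (dc == 0L & (df == 2L | dm == 2L))
      total <- total + sum(bad, na.rm = TRUE)
    } else if (have_f || have_m) {
      dp <- genotypes[, if (have_f) f else m]
      bad <- (dc == 2L & dp == 0L) | (dc == 0L & dp == 2L)
      total <- total + sum(bad, na.rm = TRUE)
    }
  }
  total
}

.FATES <- c("survive", "die_presence", "die_region", "die_maf", "die_cadd",
            "die_constraint")

#' Specify a planted variant
#'
#' Declares the carriers and the intended cascade fate of a variant to be
#' planted into a synthetic study. Planting bypasses gene dropping — the
#' dosage is 1 exactly for `carriers` and 0 elsewhere — because candidate
#' variants are defined by their observed carrier subsets, not by
#' transmission probability. Annotation overrides default to values that
#' realize the intended fate unambiguously (decoys sit clearly beyond the
#' relevant threshold; all other filters pass).
#'
#' @param carriers character vector of carrier individual ids.
#' @param fate one of `"survive"`, `"die_presence"`, `"die_region"`,
#'   `"die_maf"`, `"die_cadd"` (the pathogenicity stage; applies to indels
#'   too), `"die_constraint"`.
#' @param gene optional gene symbol override.
#' @param maf,cadd_phred,region_class,consequence_class,splice_affecting,variant_class,sift_indel,provean_indel
#'   optional annotation overrides.
#' @return A `planted_variant` specification list.
#' @export
planted_variant <- function(carriers, fate = "survive", gene = NULL,
                            maf = NULL, cadd_phred = NULL, region_class = NULL,
                            consequence_class = NULL, splice_affecting = NULL,
                            variant_class = NULL, sift_indel = NULL,
                            provean_indel = NULL) {
  fate <- match.arg(fate, .FATES)
  structure(list(carriers = as.character(carriers), fate = fate, gene = gene,
                 maf = maf, cadd_phred = cadd_phred, region_class = region_class,
                 consequence_class = consequence_class,
                 splice_affecting = splice_affecting,
                 variant_class = variant_class, sift_indel = sift_indel,
                 provean_indel = provean_indel),
            class = "planted_variant")
}

#' Realize a planted variant against a pedigree
#'
#' Builds the annotated variant row and the dosage vector encoding a
#' [planted_variant()] specification, checking that the carrier set is
#' consistent with the intended fate: every fate except `die_presence`
#' requires the proband to carry the variant and no unaffected member to,
#' while `die_presence` requires the opposite.
#'
#' @param pv a [planted_variant()].
#' @param ped an `hbm_pedigree`.
#' @param variant_id,chrom,pos identity and placement of the emitted
#'   variant.
#' @param cfg the [filter_config()] whose thresholds the planted
#'   annotations are set against.
#' @return List with `variant` (one-row [annotated_variants()] table) and
#'   `dosage` (named integer vector over pedigree members).
#' @export
plant_variant <- function(pv, ped, variant_id = "PV1", chrom = "S1",
                          pos = 1000L, cfg = filter_config()) {
  stopifnot(inherits(pv, "planted_variant"), inherits(ped, "hbm_pedigree"))
  ids <- ped$individual_id
  unknown <- setdiff(pv$carriers, ids)
  if (length(unknown) > 0L) {
    stop("planted carriers not in pedigree: ", paste(unknown, collapse = ", "))
  }
  passes_presence <- proband_id(ped) %in% pv$carriers &&
    !any(unaffected_ids(ped) %in% pv$carriers)
  if (pv$fate == "die_presence" && passes_presence) {
    stop("unsatisfiable plant: fate die_presence but carriers pass the ",
         "dominant presence filter")
  }
  if (pv$fate != "die_presence" && !passes_presence) {
    stop("unsatisfiable plant: fate ", pv$fate, " requires carriers that ",
         "pass the dominant presence filter (proband in, unaffected out)")
  }

  ov <- function(x, default) if (is.null(x)) default else x
  vclass <- ov(pv$variant_class, "snv")
  v <- list(
    region_class = ov(pv$region_class, "coding"),
    consequence_class = ov(pv$consequence_class, "missense"),
    splice_affecting = ov(pv$splice_affecting, NA),
    maf = ov(pv$maf, cfg$maf_max / 10),
    cadd_phred = ov(pv$cadd_phred, if (vclass == "snv") cfg$cadd_min + 5 else NA_real_),
    sift_indel = ov(pv$sift_indel,
                    if (vclass == "indel") "damaging" else NA_character_),
    provean_indel = ov(pv$provean_indel,
                       if (vclass == "indel") "deleterious" else NA_character_)
  )
  if (pv$fate == "die_region" && is.null(pv$region_class) &&
      is.null(pv$consequence_class)) {
    v$region_class <- "intergenic"
  }
  if (pv$fate == "die_maf" && is.null(pv$maf)) v$maf <- cfg$maf_max * 1.2
  if (pv$fate == "die_cadd") {
    if (vclass == "snv") {
      if (is.null(pv$cadd_phred)) v$cadd_phred <- cfg$cadd_min * 0.8
    } else {
      # fails under either indel rule
      if (is.null(pv$sift_indel)) v$sift_indel <- "neutral"
      if (is.null(pv$provean_indel)) v$provean_indel <- "neutral"
    }
  }
  variant <- annotated_variants(data.frame(
    chrom = chrom, pos = as.integer(pos),
    ref = if (vclass == "snv") "A" else "AT",
    alt = if (vclass == "snv") "G" else "A",
    gene = ov(pv$gene, paste0("GENE_", variant_id)),
    region_class = v$region_class, consequence_class = v$consequence_class,
    splice_affecting = v$splice_affecting, maf = v$maf,
    cadd_phred = v$cadd_phred, sift_indel = v$sift_indel,
    provean_indel = v$provean_indel, variant_id = variant_id,
    stringsAsFactors = FALSE
  ))
  dosage <- setNames(ifelse(ids %in% pv$carriers, 1L, 0L), ids)
  list(variant = variant, dosage = dosage)
}

#' Default planted-variant set of the synthetic study
#'
#' Mirrors the study's post-cascade structure: 38 surviving variants
#' distributed 4/11/9/14 over the four affected-sharing cells (all three
#' affected; proband + mother; proband + affected daughter; proband only),
#' including the additive-pair configuration — one survivor shared by
#' proband and mother and one by proband and daughter — plus 25 decoys,
#' five dying at each cascade stage (presence, region/consequence,
#' frequency, pathogenicity including two indels with neutral predictions,
#' constraint).
#'
#' @param constrained_genes gene symbols carried by the `die_constraint`
#'   decoys; must appear in the study's constraint table beyond threshold.
#' @return List of [planted_variant()] specifications.
#' @export
default_planted <- function(constrained_genes = paste0("CONSTRG", 1:5)) {
  cells <- list(
    all3 = c("I.1", "II.5", "III.1"),
    pm = c("I.1", "II.5"),
    pd = c("II.5", "III.1"),
    p = "II.5"
  )
  n_per_cell <- c(all3 = 4L, pm = 11L, pd = 9L, p = 14L)
  planted <- list()
  for (cell in names(cells)) {
    for (i in seq_len(n_per_cell[[cell]])) {
      planted[[length(planted) + 1L]] <- planted_variant(
        carriers = cells[[cell]], fate = "survive",
        maf = 0.00005 * i, cadd_phred = 20 + (i %% 10) + 0.5)
    }
  }
  # decoys: five per death stage
  die_presence_carriers <- list(
    c("II.5", "III.2"), c("II.5", "III.3"), c("II.5", "II.1"),
    c("I.1"), c("I.1", "II.5", "III.3"))
  for (cc in die_presence_carriers) {
    planted[[length(planted) + 1L]] <- planted_variant(cc, fate = "die_presence")
  }
  die_region_cfg <- list(
    list(region_class = "intergenic"),
    list(region_class = "utr3"),
    list(region_class = "ncRNA"),
    list(region_class = "coding", consequence_class = "synonymous"),
    list(region_class = "intronic", splice_affecting = FALSE,
         consequence_class = "other"))
  for (rc in die_region_cfg) {
    planted[[length(planted) + 1L]] <- do.call(planted_variant, c(
      list(carriers = "II.5", fate = "die_region"), rc))
  }
  for (i in 1:5) {
    planted[[length(planted) + 1L]] <- planted_variant(
      "II.5", fate = "die_maf", maf = 0.005 * (1.2 + 0.2 * i))
  }
  planted[[length(planted) + 1L]] <- planted_variant("II.5", fate = "die_cadd",
                                                     cadd_phred = 16)
  planted[[length(planted) + 1L]] <- planted_variant("II.5", fate = "die_cadd",
                                                     cadd_phred = 10)
  planted[[length(planted) + 1L]] <- planted_variant("II.5", fate = "die_cadd",
                                                     cadd_phred = 19.9)
  planted[[length(planted) + 1L]] <- planted_variant("II.5", fate = "die_cadd",
                                                     variant_class = "indel")
  planted[[length(planted) + 1L]] <- planted_variant(c("I.1", "II.5"),
                                                     fate = "die_cadd",
                                                     variant_class = "indel")
  for (g in constrained_genes) {
    planted[[length(planted) + 1L]] <- planted_variant("II.5",
                                                       fate = "die_constraint",
                                                       gene = g)
  }
  planted
}

#' Specify a synthetic study
#'
#' Bundles everything [generate_study()] needs: the pedigree, the planted
#' variants, the number of gene-dropped background variants, the founder
#' allele-frequency distribution (log-uniform), background annotation
#' distribution parameters, the filter configuration whose thresholds
#' planted decoys are set against, and the seed. A fixed seed makes the
#' generated files byte-identical across runs.
#'
#' @param pedigree an `hbm_pedigree` (default [study_pedigree()]).
#' @param planted list of [planted_variant()] (default [default_planted()]).
#' @param n_background number of gene-dropped background variants.
#' @param founder_maf_range range of the log-uniform founder allele
#'   frequency distribution for background variants.
#' @param background_indel_fraction fraction of background variants that
#'   are indels.
#' @param cadd_range range of the uniform CADD phred distribution for
#'   background variants.
#' @param filter_cfg a [filter_config()].
#' @param seed integer seed.
#' @return A `simulation_spec` list.
#' @export
simulation_spec <- function(pedigree = study_pedigree(),
                            planted = default_planted(),
                            n_background = 0L,
                            founder_maf_range = c(1e-5, 0.5),
                            background_indel_fraction = 0.1,
                            cadd_range = c(0, 40),
                            filter_cfg = filter_config(),
                            seed = 1L) {
  stopifnot(inherits(pedigree, "hbm_pedigree"), n_background >= 0,
            founder_maf_range[1] > 0, founder_maf_range[2] <= 1,
            founder_maf_range[1] <= founder_maf_range[2])
  structure(list(pedigree = pedigree, planted = planted,
                 n_background = as.integer(n_background),
                 founder_maf_range = founder_maf_range,
                 background_indel_fraction = background_indel_fraction,
                 cadd_range = cadd_range, filter_cfg = filter_cfg,
                 seed = as.integer(seed)),
            class = "simulation_spec")
}

# The generator's own declaration of a variant's cascade fate, evaluated
# directly from its annotations and dosages in fixed stage order.
.expected_fate <- function(v, dosage, ped, cfg, constraint, policy) {
  aff <- sort(affected_ids(ped))
  carriers <- names(dosage)[.presence(dosage, policy)]
  pro_ok <- proband_id(ped) %in% carriers
  unaff_hit <- any(unaffected_ids(ped) %in% carriers)
  if (!pro_ok || unaff_hit) return(list(fate = "die_presence", cell = "none"))
  splice <- isTRUE(v$splice_affecting)
  if (v$region_class %in% cfg$excluded_region_classes ||
      (cfg$intronic_requires_splice_flag && v$region_class == "intronic" && !splice) ||
      (cfg$exclude_synonymous && !is.na(v$consequence_class) &&
       v$consequence_class == "synonymous")) {
    return(list(fate = "die_region", cell = "none"))
  }
  if (!is.na(v$maf) && v$maf > cfg$maf_max) {
    return(list(fate = "die_maf", cell = "none"))
  }
  dies_path <- if (v$variant_class == "snv") {
    is.na(v$cadd_phred) || v$cadd_phred < cfg$cadd_min
  } else {
    sift_dmg <- !is.na(v$sift_indel) && v$sift_indel == "damaging"
    prov_dmg <- !is.na(v$provean_indel) && v$provean_indel == "deleterious"
    no_pred <- is.na(v$sift_indel) && is.na(v$provean_indel)
    kept <- if (cfg$indel_rule == "either_damaging") sift_dmg || prov_dmg
            else sift_dmg && prov_dmg
    if (cfg$missing_annotation_policy == "keep") kept <- kept || no_pred
    !kept
  }
  if (dies_path) return(list(fate = "die_cadd", cell = "none"))
  metric <- constraint[v$gene]
  enriched <- if (cfg$constraint_metric == "missense_oe") {
    !is.na(metric) && metric > cfg$constraint_threshold
  } else {
    !is.na(metric) && metric < cfg$constraint_threshold
  }
  if (isTRUE(enriched)) return(list(fate = "die_constraint", cell = "none"))
  list(fate = "survive", cell = .cell_key(intersect(carriers, aff)))
}

#' Generate a synthetic annotated study
#'
#' Emits a complete synthetic study into `dir`: a multi-sample annotated
#' VCF (`study.vcf`) holding the planted variants and `n_background`
#' gene-dropped background variants at shuffled positions on synthetic
#' contigs (`S1`–`S3`, coordinates that collide with no real genome), the
#' extended PED file (`study.ped`), a gnomAD-style gene constraint table
#' (`gene_constraint.tsv`, synthetic), and the truth table (`truth.tsv`)
#' recording every emitted variant's intended cascade fate and, for
#' survivors, its intended affected-sharing cell. Output is byte-identical
#' across runs with the same spec and seed.
#'
#' @param spec a [simulation_spec()].
#' @param dir output directory (created if needed).
#' @return List with the four file paths (`vcf`, `ped`, `truth`,
#'   `gene_constraint`) and the in-memory `variants`, `genotypes`,
#'   `truth_table` and `constraint` vector.
#' @export
generate_study <- function(spec, dir) {
  stopifnot(inherits(spec, "simulation_spec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(spec$seed)
  ped <- spec$pedigree
  cfg <- spec$filter_cfg
  policy <- segregation_policy()
  ids <- ped$individual_id

  # synthetic constraint table: five missense-enriched genes plus a few
  # tolerant ones, so both drop and keep paths are exercised
  constraint <- c(setNames(c(1.5, 1.6, 1.8, 2.0, 1.4), paste0("CONSTRG", 1:5)),
                  setNames(c(0.8, 0.95, 1.1), paste0("TOLG", 1:3)))

  n_planted <- length(spec$planted)
  n_total <- n_planted + spec$n_background
  contigs <- c("S1", "S2", "S3")
  chrom_all <- sample(contigs, n_total, replace = TRUE)
  pos_all <- sample(10000:999999, n_total, replace = FALSE)

  variants <- vector("list", n_total)
  dosages <- matrix(0L, nrow = n_total, ncol = length(ids),
                    dimnames = list(NULL, ids))
  truth <- data.frame(variant_id = character(n_total),
                      intended_fate = character(n_total),
                      intended_cell = character(n_total),
                      stringsAsFactors = FALSE)

  for (i in seq_len(n_planted)) {
    pv <- spec$planted[[i]]
    vid <- sprintf("PL%03d", i)
    pl <- plant_variant(pv, ped, variant_id = vid, chrom = chrom_all[i],
                        pos = pos_all[i], cfg = cfg)
    variants[[i]] <- as.data.frame(pl$variant)
    dosages[i, ] <- pl$dosage[ids]
    cell <- if (pv$fate == "survive") {
      .cell_key(intersect(pv$carriers, affected_ids(ped)))
    } else "none"
    truth[i, ] <- c(vid, pv$fate, cell)
  }

  if (spec$n_background > 0L) {
    r <- spec$founder_maf_range
    fmaf <- exp(runif(spec$n_background, log(r[1]), log(r[2])))
    gm <- simulate_genotype_matrix(ped, fmaf)
    gene_pool <- c(paste0("BGENE", sprintf("%03d", 1:40)), names(constraint))
    for (j in seq_len(spec$n_background)) {
      i <- n_planted + j
      vid <- sprintf("BG%03d", j)
      is_indel <- runif(1) < spec$background_indel_fraction
      region <- sample(.REGION_LEVELS, 1,
                       prob = c(0.5, 0.08, 0.04, 0.05, 0.05, 0.05, 0.05, 0.15, 0.03))
      csq <- if (region != "coding") {
        "other"
      } else if (is_indel) {
        sample(c("frameshift", "inframe_indel"), 1)
      } else {
        sample(c("missense", "synonymous", "nonsense"), 1, prob = c(0.6, 0.3, 0.1))
      }
      v <- data.frame(
        chrom = chrom_all[i], pos = pos_all[i],
        ref = if (is_indel) "AT" else "A", alt = if (is_indel) "A" else "G",
        gene = sample(gene_pool, 1), region_class = region,
        consequence_class = csq,
        splice_affecting = if (region == "intronic") runif(1) < 0.2 else NA,
        maf = fmaf[j],
        cadd_phred = if (is_indel) NA_real_ else
          round(runif(1, spec$cadd_range[1], spec$cadd_range[2]), 1),
        sift_indel = if (is_indel) sample(c("damaging", "neutral"), 1) else
          NA_character_,
        provean_indel = if (is_indel) sample(c("deleterious", "neutral"), 1) else
          NA_character_,
        variant_id = vid,
        variant_class = if (is_indel) "indel" else "snv",
        stringsAsFactors = FALSE)
      variants[[i]] <- v
      dosages[i, ] <- gm[j, ids]
      fate <- .expected_fate(v, dosages[i, ], ped, cfg, constraint, policy)
      truth[i, ] <- c(vid, fate$fate, fate$cell)
    }
  }

  var_tab <- if (n_total == 0L) .empty_variants() else
    annotated_variants(do.call(rbind, variants))
  rownames(dosages) <- var_tab$variant_id

  paths <- list(vcf = file.path(dir, "study.vcf"),
                ped = file.path(dir, "study.ped"),
                truth = file.path(dir, "truth.tsv"),
                gene_constraint = file.path(dir, "gene_constraint.tsv"))
  write_annotated_vcf(var_tab, dosages, paths$vcf)
  write_pedigree(ped, paths$ped)
  write.table(truth, paths$truth, sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(c("#gene\tmetric",
               paste(names(constraint), format(constraint, trim = TRUE),
                     sep = "\t")),
             paths$gene_constraint)
  c(paths, list(variants = var_tab, genotypes = dosages, truth_table = truth,
                constraint = constraint))
}
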