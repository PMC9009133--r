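cfg <- filter_config()

test_that("region/consequence filter keeps coding non-synonymous, drops the rest", {
  keep <- region_consequence_filter(bind_variants(
    make_variant("m", consequence_class = "missense"),
    make_variant("s", consequence_class = "synonymous"),
    make_variant("i1", region_class = "intronic", consequence_class = "other",
                 splice_affecting = TRUE),
    make_variant("i2", region_class = "intronic", consequence_class = "other",
                 splice_affecting = FALSE),
    make_variant("i3", region_class = "intronic", consequence_class = "other",
                 splice_affecting = NA),  # no prediction = not splice-affecting
    make_variant("x1", region_class = "intergenic"),
    make_variant("x2", region_class = "utr5"),
    make_variant("x3", region_class = "downstream"),
    make_variant("x4", region_class = "unknown")), cfg)
  expect_identical(keep, c(TRUE, FALSE, TRUE, FALSE, FALSE,
                           FALSE, FALSE, FALSE, FALSE))
})

test_that("frequency filter keeps rare and frequency-less variants", {
  mafs <- c(0.00015, 0.00401, 0.005, 0.006, NA)
  keep <- frequency_filter(bind_variants(
    make_variant("a", maf = mafs[1]), make_variant("b", maf = mafs[2]),
    make_variant("c", maf = mafs[3]), make_variant("d", maf = mafs[4]),
    make_variant("e", maf = mafs[5])), cfg)
  expect_identical(keep, c(TRUE, TRUE, TRUE, FALSE, TRUE))
})

test_that("SNV pathogenicity uses the CADD threshold; absent CADD drops", {
  keep <- pathogenicity_filter(bind_variants(
    make_variant("a", cadd_phred = 23.1),
    make_variant("b", cadd_phred = 20),
    make_variant("c", cadd_phred = 19.9),
    make_variant("d", cadd_phred = NA)), cfg)
  expect_identical(keep, c(TRUE, TRUE, FALSE, FALSE))
})

test_that("indel rule matches the enumerated prediction truth table", {
  combos <- expand.grid(sift = c("damaging", "neutral"),
                        provean = c("deleterious", "neutral"),
                        stringsAsFactors = FALSE)
  vars <- do.call(bind_variants, lapply(seq_len(nrow(combos)), function(i) {
    make_variant(paste0("ind", i), ref = "AT", alt = "A",
                 consequence_class = "frameshift", cadd_phred = NA,
                 sift_indel = combos$sift[i], provean_indel = combos$provean[i])
  }))
  # frozen by hand-enumeration of the four combinations under each rule
  either <- pathogenicity_filter(vars, filter_config(indel_rule = "either_damaging"))
  both <- pathogenicity_filter(vars, filter_config(indel_rule = "both_damaging"))
  expect_identical(either, c(TRUE, TRUE, TRUE, FALSE))
  expect_identical(both, c(TRUE, FALSE, FALSE, FALSE))
  # missing predictions follow the missing-annotation policy
  nopred <- make_variant("np", ref = "AT", alt = "A", cadd_phred = NA,
                         consequence_class = "frameshift")
  expect_true(pathogenicity_filter(nopred, cfg))
  expect_false(pathogenicity_filter(
    nopred, filter_config(missing_annotation_policy = "drop")))
})

test_that("constraint filter drops missense-enriched genes, keeps unknown genes", {
  constraint <- c(G_hi = 1.5, G_lo = 1.0, Z_lo = -4, Z_hi = 2)
  vars <- bind_variants(make_variant("a", gene = "G_hi"),
                        make_variant("b", gene = "G_lo"),
                        make_variant("c", gene = "G_absent"))
  expect_identical(constraint_filter(vars, constraint, cfg),
                   c(FALSE, TRUE, TRUE))
  zcfg <- filter_config(constraint_metric = "missense_z",
                        constraint_threshold = -3)
  zvars <- bind_variants(make_variant("a", gene = "Z_lo"),
                         make_variant("b", gene = "Z_hi"),
                         make_variant("c", gene = "Z_absent"))
  expect_identical(constraint_filter(zvars, constraint, zcfg),
                   c(FALSE, TRUE, TRUE))
  expect_true(all(constraint_filter(vars, NULL, cfg)))
})

test_that("annotation filters are order-invariant per-variant predicates", {
  set.seed(101)
  ped <- study_pedigree()
  constraint <- c(CG1 = 1.5, CG2 = 0.9)
  for (rep in 1:20) {
    n <- 30
    vars <- do.call(bind_variants, lapply(seq_len(n), function(i) {
      make_variant(paste0("v", i), pos = 100L + i,
                   gene = sample(c("CG1", "CG2", paste0("G", i)), 1),
                   region_class = sample(c("coding", "intronic", "intergenic"), 1),
                   consequence_class = sample(c("missense", "synonymous", "other"), 1),
                   splice_affecting = sample(c(TRUE, FALSE, NA), 1),
                   maf = sample(c(NA, 0.001, 0.01), 1),
                   cadd_phred = sample(c(NA, 15, 25), 1))
    }))
    filters <- list(
      function(v) region_consequence_filter(v, cfg),
      function(v) frequency_filter(v, cfg),
      function(v) pathogenicity_filter(v, cfg),
      function(v) constraint_filter(v, constraint, cfg))
    ref_keep <- Reduce(`&`, lapply(filters, function(f) f(vars)))
    perm_keep <- Reduce(`&`, lapply(filters[sample(4)], function(f) f(vars)))
    expect_identical(perm_keep, ref_keep)
  }
})

test_that("relaxing cadd_min or maf_max never shrinks the survivor set", {
  set.seed(202)
  vars <- do.call(bind_variants, lapply(1:50, function(i) {
    make_variant(paste0("v", i), pos = 100L + i,
                 maf = runif(1, 0, 0.02), cadd_phred = runif(1, 0, 40))
  }))
  for (cadds in list(c(30, 20), c(20, 10), c(25, 0))) {
    n_strict <- sum(pathogenicity_filter(vars, filter_config(cadd_min = cadds[1])))
    n_loose <- sum(pathogenicity_filter(vars, filter_config(cadd_min = cadds[2])))
    expect_gte(n_loose, n_strict)
  }
  for (mafs in list(c(0.001, 0.005), c(0.005, 0.02), c(0.002, 1))) {
    n_strict <- sum(frequency_filter(vars, filter_config(maf_max = mafs[1])))
    n_loose <- sum(frequency_filter(vars, filter_config(maf_max = mafs[2])))
    expect_gte(n_loose, n_strict)
  }
})

test_that("run_cascade traces conserve variants and stage counts chain", {
  st <- generate_study(simulation_spec(seed = 5, n_background = 40), tempfile())
  ped <- study_pedigree()
  res <- run_cascade(st$variants, st$genotypes, ped,
                     gene_constraint = st$constraint)
  tr <- res$trace
  expect_identical(tr$stage, c("dominant_presence", "region_consequence",
                               "frequency", "pathogenicity", "constraint"))
  expect_true(all(tr$n_out <= tr$n_in))
  expect_identical(tr$n_in[-1], tr$n_out[-5])
  dropped <- unlist(tr$dropped)
  expect_equal(length(dropped), tr$n_in[1] - tr$n_out[5])
  expect_false(anyDuplicated(dropped) > 0)
  expect_setequal(c(dropped, res$survivors$variant_id), st$variants$variant_id)
})

test_that("neutral annotation filters reduce the cascade to dominant presence", {
  st <- generate_study(simulation_spec(seed = 6, n_background = 30), tempfile())
  ped <- study_pedigree()
  neutral <- filter_config(maf_max = 1, cadd_min = 0,
                           excluded_region_classes = character(0),
                           exclude_synonymous = FALSE,
                           intronic_requires_splice_flag = FALSE,
                           missing_annotation_policy = "keep")
  res <- run_cascade(st$variants, st$genotypes, ped, neutral,
                     gene_constraint = NULL)
  keep_presence <- dominant_presence(st$variants$variant_id, st$genotypes, ped)
  # SNVs with no CADD and indels with neutral predictions can still die at
  # the pathogenicity stage; exclude pathogenicity effects via cfg already
  expect_setequal(res$survivors$variant_id,
                  st$variants$variant_id[keep_presence &
                                           pathogenicity_filter(st$variants, neutral)])
})

test_that("an empty variant list yields empty survivors and an all-zero trace", {
  st <- generate_study(simulation_spec(seed = 1, planted = list()), tempfile())
  res <- run_cascade(st$variants, st$genotypes, study_pedigree())
  expect_equal(nrow(res$survivors), 0)
  expect_true(all(res$trace$n_in == 0) && all(res$trace$n_out == 0))
})
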