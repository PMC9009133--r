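test_that("degenerate founder frequencies give all-reference / all-alt genotypes", {
  ped <- study_pedigree()
  expect_true(all(simulate_genotypes(ped, 0, seed = 1) == 0L))
  expect_true(all(simulate_genotypes(ped, 1, seed = 1) == 2L))
  expect_error(simulate_genotype_matrix(ped, -0.1), "\\[0, 1\\]")
  expect_error(simulate_genotype_matrix(ped, 1.5), "\\[0, 1\\]")
})

test_that("gene dropping is Mendelian over 10,000 transmissions", {
  # three-generation pedigree with both parents present, so every
  # transmission is fully checkable
  ped3 <- pedigree(data.frame(
    family_id = "F",
    individual_id = c("gf", "gm", "f", "m", "c1", "c2", "c3"),
    father_id = c("0", "0", "gf", "0", "f", "f", "f"),
    mother_id = c("0", "0", "gm", "0", "m", "m", "m"),
    sex = c("male", "female", "male", "female", "female", "male", "female"),
    affected = c("unknown", "unknown", "affected", "unaffected",
                 "affected", "unaffected", "unaffected"),
    z_ls = NA_real_, z_fn = NA_real_, stringsAsFactors = FALSE), "f")
  mafs <- rep(c(0.05, 0.2, 0.5, 0.8), length.out = 10000)
  gm <- simulate_genotype_matrix(ped3, mafs, seed = 99)
  expect_equal(dim(gm), c(10000, 7))
  expect_identical(mendelian_violations(gm, ped3), 0L)
  # the violation counter itself detects a planted non-Mendelian genotype
  bad <- gm
  bad[1, c("f", "m", "c1")] <- c(0L, 0L, 2L)
  expect_gt(mendelian_violations(bad, ped3), 0)
})

test_that("planted variants land exactly on their intended carriers and fates", {
  ped <- study_pedigree()
  pl <- plant_variant(planted_variant(c("I.1", "II.5"), "survive"), ped,
                      variant_id = "pv", chrom = "S1", pos = 500L)
  expect_identical(pl$dosage[c("I.1", "II.5")], c(I.1 = 1L, II.5 = 1L))
  expect_true(all(pl$dosage[c("II.1", "III.1", "III.2", "III.3")] == 0L))
  expect_true(frequency_filter(pl$variant) && pathogenicity_filter(pl$variant) &&
                region_consequence_filter(pl$variant))

  cadd_decoy <- plant_variant(planted_variant("II.5", "die_cadd"), ped)
  expect_false(pathogenicity_filter(cadd_decoy$variant))
  expect_true(frequency_filter(cadd_decoy$variant))

  maf_decoy <- plant_variant(planted_variant("II.5", "die_maf"), ped)
  expect_false(frequency_filter(maf_decoy$variant))

  indel_decoy <- plant_variant(planted_variant("II.5", "die_cadd",
                                               variant_class = "indel"), ped)
  expect_false(pathogenicity_filter(indel_decoy$variant,
                                    filter_config(indel_rule = "either_damaging")))
  expect_false(pathogenicity_filter(indel_decoy$variant,
                                    filter_config(indel_rule = "both_damaging")))

  pres_decoy <- plant_variant(planted_variant(c("II.5", "III.2"), "die_presence"),
                              ped)
  gm <- matrix(pres_decoy$dosage, nrow = 1,
               dimnames = list("d", names(pres_decoy$dosage)))
  expect_false(dominant_presence("d", gm, ped))

  # unsatisfiable fate/carrier combinations are rejected
  expect_error(plant_variant(planted_variant(c("II.5", "III.2"), "survive"), ped),
               "unsatisfiable")
  expect_error(plant_variant(planted_variant(c("I.1", "II.5"), "die_presence"), ped),
               "unsatisfiable")
  expect_error(plant_variant(planted_variant("nobody", "survive"), ped),
               "not in pedigree")
})

test_that("generated studies are byte-identical under a fixed seed", {
  spec <- simulation_spec(seed = 123, n_background = 25)
  d1 <- tempfile(); d2 <- tempfile()
  s1 <- generate_study(spec, d1)
  s2 <- generate_study(spec, d2)
  for (f in c("vcf", "ped", "truth", "gene_constraint")) {
    expect_identical(readLines(s1[[f]]), readLines(s2[[f]]), info = f)
  }
  # and a different seed changes the VCF
  s3 <- generate_study(simulation_spec(seed = 124, n_background = 25), tempfile())
  expect_false(identical(readLines(s1$vcf), readLines(s3$vcf)))
})

test_that("an empty spec still produces a valid, loadable study", {
  st <- generate_study(simulation_spec(seed = 1, planted = list()), tempfile())
  got <- read_annotated_vcf(st$vcf)
  expect_equal(nrow(got$variants), 0)
  expect_equal(nrow(st$truth_table), 0)
  expect_equal(nrow(read_pedigree(st$ped, "II.5")), 6)
})

test_that("the full pipeline recovers every intended fate and cell (truth recovery)", {
  st <- generate_study(simulation_spec(seed = 42, n_background = 50), tempfile())
  out <- tempfile()
  res <- suppressMessages(run_pipeline(pipeline_config(
    vcf = st$vcf, ped = st$ped, proband_id = "II.5", out_dir = out,
    gene_constraint = st$gene_constraint)))
  truth <- st$truth_table
  expect_setequal(res$survivors$variant_id,
                  truth$variant_id[truth$intended_fate == "survive"])
  # every dropped variant died at its intended stage
  fate_stage <- c(die_presence = "dominant_presence",
                  die_region = "region_consequence", die_maf = "frequency",
                  die_cadd = "pathogenicity", die_constraint = "constraint")
  for (fate in names(fate_stage)) {
    stage_idx <- which(res$trace$stage == fate_stage[[fate]])
    expect_setequal(res$trace$dropped[[stage_idx]],
                    truth$variant_id[truth$intended_fate == fate])
  }
  # every survivor sits in its intended affected-sharing cell
  cell_of <- setNames(truth$intended_cell, truth$variant_id)
  for (key in names(res$partition$cells)) {
    expect_true(all(cell_of[res$partition$cells[[key]]] == key))
  }
})

test_that("a planted additive pair is always reported, uniquely when alone", {
  ped <- study_pedigree()
  minimal <- simulation_spec(seed = 9, planted = list(
    planted_variant(c("I.1", "II.5"), "survive"),
    planted_variant(c("II.5", "III.1"), "survive")))
  st <- generate_study(minimal, tempfile())
  res <- suppressMessages(run_pipeline(pipeline_config(
    vcf = st$vcf, ped = st$ped, proband_id = "II.5", out_dir = tempfile(),
    gene_constraint = st$gene_constraint)))
  expect_equal(nrow(res$pairs), 1)
  expect_identical(res$pairs$covered, "I.1,II.5,III.1")
  # in the full default study the planted pair is still among those reported
  stf <- generate_study(simulation_spec(seed = 9), tempfile())
  resf <- suppressMessages(run_pipeline(pipeline_config(
    vcf = stf$vcf, ped = stf$ped, proband_id = "II.5", out_dir = tempfile(),
    gene_constraint = stf$gene_constraint)))
  expect_true(all(c("I.1,II.5", "II.5,III.1") %in%
                    c(resf$pairs$carriers_a, resf$pairs$carriers_b)))
  expect_gt(nrow(resf$pairs), 0)
})
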