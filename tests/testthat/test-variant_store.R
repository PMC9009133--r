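# Inline six-sample VCF exercising GT decoding, multiallelic decomposition
# and missing-annotation handling.
write_test_vcf <- function(extra_records = character(0),
                           drop_info = character(0)) {
  info_defs <- c(
    GENE = "##INFO=<ID=GENE,Number=A,Type=String,Description=\"g\">",
    REGION = "##INFO=<ID=REGION,Number=A,Type=String,Description=\"r\">",
    CSQ = "##INFO=<ID=CSQ,Number=A,Type=String,Description=\"c\">",
    SPLICE = "##INFO=<ID=SPLICE,Number=A,Type=Integer,Description=\"s\">",
    MAF = "##INFO=<ID=MAF,Number=A,Type=Float,Description=\"m\">",
    CADD = "##INFO=<ID=CADD,Number=A,Type=Float,Description=\"p\">",
    SIFT_IND = "##INFO=<ID=SIFT_IND,Number=A,Type=String,Description=\"si\">",
    PROVEAN_IND = "##INFO=<ID=PROVEAN_IND,Number=A,Type=String,Description=\"pv\">")
  f <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=S1>",
    info_defs[setdiff(names(info_defs), drop_info)],
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"gt\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "I.1", "II.1", "II.5", "III.1", "III.2", "III.3"),
          collapse = "\t"),
    paste(c("S1", "100", "rs1", "A", "G", ".", "PASS",
            "GENE=GA;REGION=coding;CSQ=missense;MAF=0.0001;CADD=25",
            "GT", "0/0", "0/0", "0/1", "0/0", "0/0", "0/0"), collapse = "\t"),
    paste(c("S1", "200", "v2", "G", "A,C", ".", "PASS",
            "GENE=GB,GC;REGION=coding,coding;CSQ=missense,synonymous;MAF=0.001,0.002;CADD=21,22",
            "GT", "1/2", "0/1", "0|2", "./.", "./1", "0/0"), collapse = "\t"),
    extra_records), f)
  f
}

test_that("GT decoding yields the expected dosage vector per sample", {
  got <- read_annotated_vcf(write_test_vcf())
  expect_identical(unname(got$genotypes["rs1", ]), c(0L, 0L, 1L, 0L, 0L, 0L))
  expect_identical(got$sample_ids,
                   c("I.1", "II.1", "II.5", "III.1", "III.2", "III.3"))
  v1 <- got$variants[got$variants$variant_id == "rs1", ]
  expect_identical(v1$gene, "GA")
  expect_equal(v1$maf, 1e-4)
  expect_identical(v1$variant_class, "snv")
})

test_that("multiallelic records decompose with per-alt annotations and dosages", {
  got <- read_annotated_vcf(write_test_vcf())
  expect_equal(nrow(got$variants), 3)
  a1 <- got$variants[got$variants$alt == "A" & got$variants$pos == 200, ]
  a2 <- got$variants[got$variants$alt == "C", ]
  expect_identical(a1$gene, "GB")
  expect_identical(a2$gene, "GC")
  expect_identical(a2$consequence_class, "synonymous")
  # sample I.1 has GT 1/2: dosage 1 for each decomposed allele
  expect_identical(unname(got$genotypes[a1$variant_id, "I.1"]), 1L)
  expect_identical(unname(got$genotypes[a2$variant_id, "I.1"]), 1L)
  # phased 0|2 decodes like unphased
  expect_identical(unname(got$genotypes[a2$variant_id, "II.5"]), 1L)
  # fully and half-missing genotypes are missing for every decomposed allele
  expect_true(all(is.na(got$genotypes[c(a1$variant_id, a2$variant_id), "III.1"])))
  expect_true(all(is.na(got$genotypes[c(a1$variant_id, a2$variant_id), "III.2"])))
})

test_that("decomposition conserves per-sample alt-allele counts", {
  got <- read_annotated_vcf(write_test_vcf())
  site <- got$variants$pos == 200
  gt_raw <- c(I.1 = "1/2", II.1 = "0/1", II.5 = "0|2", III.3 = "0/0")
  for (s in names(gt_raw)) {
    expected <- sum(strsplit(gt_raw[[s]], "[/|]")[[1]] %in% c("1", "2"))
    expect_equal(sum(got$genotypes[site, s]), expected, info = s)
  }
})

test_that("annotation keys absent from the header are a configuration error", {
  f <- write_test_vcf(drop_info = "CADD")
  expect_error(read_annotated_vcf(f), "CADD")
  expect_warning(got <- read_annotated_vcf(f, strict = FALSE), "CADD")
  expect_true(all(is.na(got$variants$cadd_phred)))
})

test_that("a VCF without GT is rejected", {
  f <- tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2", "##contig=<ID=S1>",
               "##INFO=<ID=GENE,Number=A,Type=String,Description=\"g\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO"), collapse = "\t"),
               paste(c("S1", "100", ".", "A", "G", ".", "PASS", "GENE=GA"),
                     collapse = "\t")), f)
  expect_error(read_annotated_vcf(f), "GT")
})

test_that("write -> read round-trips every annotated variant field", {
  vars <- bind_variants(
    make_variant("v1", pos = 100L, maf = 0.00015, cadd_phred = 23.1),
    make_variant("v2", pos = 200L, ref = "AT", alt = "A", maf = NA,
                 cadd_phred = NA, sift_indel = "damaging",
                 provean_indel = "neutral", consequence_class = "frameshift"),
    make_variant("v3", pos = 300L, region_class = "intronic",
                 consequence_class = "other", splice_affecting = TRUE))
  gm <- matrix(c(0L, 1L, NA, 1L, 0L, 2L), nrow = 3,
               dimnames = list(vars$variant_id, c("A", "B")))
  f <- tempfile(fileext = ".vcf")
  write_annotated_vcf(vars, gm, f)
  back <- read_annotated_vcf(f)
  expect_equal(as.data.frame(back$variants), as.data.frame(vars))
  expect_identical(back$genotypes[rownames(gm), colnames(gm)], gm)
})

test_that("candidate reports serialize deterministically to TSV and JSON", {
  cand <- data.frame(gene = c("VAV3", "ADGRE5"), variant_id = c("rs1", "rs2"),
                     cosegregation = c("I.1,II.5", "II.5,III.1"),
                     evidence_score = c(2L, 2L), cadd_phred = c(23.1, 28),
                     maf = c(0.00015, 0.00013))
  tsv <- tempfile(fileext = ".tsv")
  write_candidates(cand, tsv, "tsv")
  lines <- readLines(tsv)
  expect_length(lines, 3)
  expect_match(lines[1], "^gene\tvariant_id\tcosegregation")
  js <- tempfile(fileext = ".json")
  write_candidates(cand, js, "json")
  parsed <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(nrow(parsed), 2)
  expect_equal(parsed$gene, cand$gene)
  # empty candidate list -> header-only TSV
  write_candidates(cand[0, ], tsv, "tsv")
  expect_length(readLines(tsv), 1)
})
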