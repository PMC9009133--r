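.REGION_LEVELS <- c("coding", "intergenic", "utr5", "utr3", "upstream",
                    "downstream", "ncRNA", "intronic", "unknown")
.CSQ_LEVELS <- c("missense", "synonymous", "nonsense", "frameshift",
                 "inframe_indel", "splice_region", "other")

#' Validate a table of annotated variants
#'
#' Normalizes and checks the per-alt-allele variant table used throughout
#' the pipeline. One row per decomposed alt allele, with VCF 1-based
#' coordinates and the annotation fields consumed by the filter cascade.
#' Absent annotations are `NA`, never a default value: the cascade decides
#' explicitly what missingness means at each stage.
#'
#' @param df data frame with columns `chrom`, `pos`, `ref`, `alt`, `gene`,
#'   `region_class`, `consequence_class`, `splice_affecting`, `maf`,
#'   `cadd_phred`, `sift_indel`, `provean_indel`, `variant_id` (an rs number
#'   or a constructed `chrom:pos:ref:alt` key). `variant_class`
#'   (`"snv"`/`"indel"`) is derived from the allele lengths if absent.
#' @return The validated data frame with class `annotated_variants`.
#' @export
annotated_variants <- function(df) {
  req <- c("chrom", "pos", "ref", "alt", "gene", "region_class",
           "consequence_class", "splice_affecting", "maf", "cadd_phred",
           "sift_indel", "provean_indel", "variant_id")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols) > 0L) {
    stop("annotated_variants is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  v <- as.data.frame(df)
  v$chrom <- as.character(v$chrom)
  v$pos <- as.integer(v$pos)
  v$ref <- toupper(as.character(v$ref))
  v$alt <- toupper(as.character(v$alt))
  v$gene <- as.character(v$gene)
  v$variant_id <- as.character(v$variant_id)
  v$maf <- as.numeric(v$maf)
  v$cadd_phred <- as.numeric(v$cadd_phred)
  v$splice_affecting <- as.logical(v$splice_affecting)

  if (any(is.na(v$pos)) || any(v$pos < 1L)) stop("pos must be a 1-based integer")
  if (any(grepl(",", v$alt, fixed = TRUE))) {
    stop("multiallelic alt detected; decompose before constructing ",
         "annotated_variants")
  }
  if (any(v$ref == v$alt)) stop("ref == alt at ",
                                paste(v$variant_id[v$ref == v$alt], collapse = ", "))
  if (is.null(df$variant_class)) {
    v$variant_class <- ifelse(nchar(v$ref) == 1L & nchar(v$alt) == 1L,
                              "snv", "indel")
  } else {
    v$variant_class <- as.character(df$variant_class)
    implied <- ifelse(nchar(v$ref) == 1L & nchar(v$alt) == 1L, "snv", "indel")
    if (any(v$variant_class != implied)) {
      stop("variant_class inconsistent with ref/alt lengths at ",
           paste(v$variant_id[v$variant_class != implied], collapse = ", "))
    }
  }
  chk_enum <- function(x, levels, what) {
    bad <- !is.na(x) & !x %in% levels
    if (any(bad)) stop("invalid ", what, ": ", paste(unique(x[bad]), collapse = ", "))
    x
  }
  v$region_class <- chk_enum(as.character(v$region_class), .REGION_LEVELS, "region_class")
  v$consequence_class <- chk_enum(as.character(v$consequence_class), .CSQ_LEVELS,
                                  "consequence_class")
  v$sift_indel <- chk_enum(as.character(v$sift_indel), c("damaging", "neutral"),
                           "sift_indel")
  v$provean_indel <- chk_enum(as.character(v$provean_indel),
                              c("deleterious", "neutral"), "provean_indel")
  if (any(!is.na(v$maf) & (v$maf < 0 | v$maf > 1))) stop("maf outside [0,1]")
  if (any(!is.na(v$cadd_phred) & v$cadd_phred < 0)) stop("cadd_phred must be >= 0")
  if (anyDuplicated(v$variant_id)) {
    stop("duplicate variant_id: ",
         paste(unique(v$variant_id[duplicated(v$variant_id)]), collapse = ", "))
  }
  rownames(v) <- NULL
  class(v) <- c("annotated_variants", "data.frame")
  v
}

#' Default INFO-key mapping for annotated VCFs
#'
#' Maps each annotation field the pipeline consumes to the VCF INFO key
#' carrying it. This is the encoding [write_annotated_vcf()] emits; point
#' the entries at other keys to ingest VCFs annotated by other tools.
#' `splice_affecting` is encoded as an integer 0/1 INFO field
#' (`Number=A`), sidestepping per-tool differences in splice-prediction
#' encodings.
#'
#' @return Named character vector: field name -> INFO key.
#' @export
default_annotation_spec <- function() {
  c(gene = "GENE", region_class = "REGION", consequence_class = "CSQ",
    splice_affecting = "SPLICE", maf = "MAF", cadd_phred = "CADD",
    sift_indel = "SIFT_IND", provean_indel = "PROVEAN_IND")
}

# Zero-row annotated_variants table with the full column set.
.empty_variants <- function() {
  annotated_variants(data.frame(
    chrom = character(), pos = integer(), ref = character(), alt = character(),
    gene = character(), region_class = character(),
    consequence_class = character(), splice_affecting = logical(),
    maf = numeric(), cadd_phred = numeric(), sift_indel = character(),
    provean_indel = character(), variant_id = character()))
}

# Split a per-record INFO value across n_alt decomposed alleles:
# comma-lists of matching length distribute per-alt (Number=A), anything
# else replicates to every alt.
.split_info <- function(values, n_alt) {
  out <- vector("list", length(values))
  for (i in seq_along(values)) {
    if (is.na(values[i])) {
      out[[i]] <- rep(NA_character_, n_alt[i])
    } else {
      parts <- strsplit(values[i], ",", fixed = TRUE)[[1]]
      out[[i]] <- if (length(parts) == n_alt[i]) parts else
        rep(values[i], n_alt[i])
    }
  }
  unlist(out)
}

# Dosage of alt allele `k` from a GT string; any missing allele makes the
# whole genotype missing (a half-called genotype cannot certify absence).
.gt_dosage <- function(gt, k) {
  if (is.na(gt) || gt == ".") return(NA_integer_)
  toks <- strsplit(gt, "[/|]")[[1]]
  if (any(toks == ".")) return(NA_integer_)
  sum(toks == as.character(k))
}

#' Read an annotated multi-sample VCF
#'
#' Parses a VCFv4.x file (gzip-transparent, via \pkg{vcfR}), decomposes
#' multiallelic records into one row per alt allele, decodes per-sample GT
#' into alt-allele dosages (0/1/2, `NA` for fully or half-missing
#' genotypes), and extracts the annotation fields named by
#' `annotation_spec` from INFO. INFO keys absent from a record yield `NA`
#' fields — never silent defaults.
#'
#' @param path path to the VCF.
#' @param annotation_spec named character vector mapping annotation fields
#'   to INFO keys; see [default_annotation_spec()].
#' @param strict if `TRUE` (default) a spec'd INFO key missing from the VCF
#'   header is a configuration error; if `FALSE` it is downgraded to a
#'   warning and the field is `NA` throughout.
#' @return List with `variants` (an [annotated_variants()] table) and
#'   `genotypes` (integer dosage matrix, variants x samples, `NA` =
#'   missing), plus `sample_ids`.
#' @export
read_annotated_vcf <- function(path, annotation_spec = default_annotation_spec(),
                               strict = TRUE) {
  if (!file.exists(path)) stop("VCF not found: ", path)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  meta <- vcf@meta
  if (!any(grepl("##FORMAT=<ID=GT[,>]", meta))) {
    stop("VCF has no GT FORMAT definition; genotype dosages unavailable")
  }
  declared <- sub("^##INFO=<ID=([^,>]+).*", "\\1", grep("^##INFO=", meta, value = TRUE))
  for (field in names(annotation_spec)) {
    key <- annotation_spec[[field]]
    if (!key %in% declared) {
      msg <- paste0("annotation_spec key '", key, "' (field ", field,
                    ") not declared in VCF header")
      if (strict) stop(msg) else warning(msg)
    }
  }

  fix <- vcf@fix
  if (nrow(fix) == 0L) {
    gm <- matrix(integer(0), nrow = 0, ncol = length(colnames(vcf@gt)) - 1L,
                 dimnames = list(NULL, colnames(vcf@gt)[-1]))
    return(list(variants = .empty_variants(), genotypes = gm,
                sample_ids = colnames(gm)))
  }

  alts <- strsplit(fix[, "ALT"], ",", fixed = TRUE)
  n_alt <- lengths(alts)
  rec <- rep(seq_len(nrow(fix)), n_alt)        # source record per output row
  alt_k <- unlist(lapply(n_alt, seq_len))      # allele index within record

  info_field <- function(field) {
    key <- annotation_spec[[field]]
    if (is.null(key) || !key %in% declared) {
      return(rep(NA_character_, sum(n_alt)))
    }
    .split_info(vcfR::extract.info(vcf, element = key), n_alt)
  }

  id <- fix[, "ID"]
  vid <- ifelse(is.na(id) | id == ".",
                paste(fix[, "CHROM"], fix[, "POS"], fix[, "REF"], "", sep = ":"),
                id)[rec]
  # multiallelic records get a per-alt suffix so ids stay unique
  vid <- ifelse(n_alt[rec] > 1L, paste0(vid, "_", alt_k), vid)

  splice_raw <- info_field("splice_affecting")
  variants <- annotated_variants(data.frame(
    chrom = fix[rec, "CHROM"],
    pos = as.integer(fix[rec, "POS"]),
    ref = fix[rec, "REF"],
    alt = unlist(alts),
    gene = info_field("gene"),
    region_class = info_field("region_class"),
    consequence_class = info_field("consequence_class"),
    splice_affecting = ifelse(is.na(splice_raw), NA, splice_raw == "1"),
    maf = suppressWarnings(as.numeric(info_field("maf"))),
    cadd_phred = suppressWarnings(as.numeric(info_field("cadd_phred"))),
    sift_indel = info_field("sift_indel"),
    provean_indel = info_field("provean_indel"),
    variant_id = vid,
    stringsAsFactors = FALSE
  ))

  gt <- vcfR::extract.gt(vcf, element = "GT")
  samples <- colnames(gt)
  gm <- matrix(NA_integer_, nrow = nrow(variants), ncol = length(samples),
               dimnames = list(variants$variant_id, samples))
  for (i in seq_len(nrow(variants))) {
    gm[i, ] <- vapply(gt[rec[i], ], .gt_dosage, integer(1), k = alt_k[i])
  }
  list(variants = variants, genotypes = gm, sample_ids = samples)
}

#' Write variants and genotype dosages as a VCF
#'
#' Emits a minimal VCFv4.2 file with the pipeline's annotation fields as
#' INFO keys (see [default_annotation_spec()]) and per-sample GT derived
#' from dosages (0 -> 0/0, 1 -> 0/1, 2 -> 1/1, `NA` -> ./.).
#' `read_annotated_vcf()` on the result recovers every field.
#'
#' @param variants an [annotated_variants()] table.
#' @param genotypes dosage matrix (variants x samples) with rownames
#'   matching `variants$variant_id`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_annotated_vcf <- function(variants, genotypes, path) {
  stopifnot(nrow(variants) == nrow(genotypes))
  contigs <- unique(variants$chrom)
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s>", contigs),
    "##INFO=<ID=GENE,Number=A,Type=String,Description=\"Gene symbol\">",
    "##INFO=<ID=REGION,Number=A,Type=String,Description=\"Region class\">",
    "##INFO=<ID=CSQ,Number=A,Type=String,Description=\"Consequence class\">",
    "##INFO=<ID=SPLICE,Number=A,Type=Integer,Description=\"Predicted to affect splicing (0/1)\">",
    "##INFO=<ID=MAF,Number=A,Type=Float,Description=\"Population minor allele frequency\">",
    "##INFO=<ID=CADD,Number=A,Type=Float,Description=\"CADD phred score\">",
    "##INFO=<ID=SIFT_IND,Number=A,Type=String,Description=\"SIFT indel call\">",
    "##INFO=<ID=PROVEAN_IND,Number=A,Type=String,Description=\"PROVEAN indel call\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", colnames(genotypes)), collapse = "\t")
  )
  fmt_num <- function(x) format(x, trim = TRUE, digits = 10, scientific = FALSE)
  info <- vapply(seq_len(nrow(variants)), function(i) {
    v <- variants[i, ]
    parts <- c(
      paste0("GENE=", v$gene),
      paste0("REGION=", v$region_class),
      paste0("CSQ=", v$consequence_class),
      if (!is.na(v$splice_affecting)) paste0("SPLICE=", as.integer(v$splice_affecting)),
      if (!is.na(v$maf)) paste0("MAF=", fmt_num(v$maf)),
      if (!is.na(v$cadd_phred)) paste0("CADD=", fmt_num(v$cadd_phred)),
      if (!is.na(v$sift_indel)) paste0("SIFT_IND=", v$sift_indel),
      if (!is.na(v$provean_indel)) paste0("PROVEAN_IND=", v$provean_indel)
    )
    paste(parts[!is.na(parts)], collapse = ";")
  }, character(1))
  ord <- order(match(variants$chrom, contigs), variants$pos)
  body <- vapply(ord, function(i) {
    gt <- vapply(genotypes[i, ], function(d) {
      if (is.na(d)) "./." else c("0/0", "0/1", "1/1")[d + 1L]
    }, character(1))
    paste(c(variants$chrom[i], variants$pos[i], variants$variant_id[i],
            variants$ref[i], variants$alt[i], ".", "PASS", info[i], "GT",
            gt), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write a candidate report
#'
#' Serializes a ranked candidate table (see [annotate_and_rank()]) as TSV
#' with a deterministic column order mirroring the classical candidate
#' table layout (gene, variant, cosegregation, evidence, pathogenicity,
#' frequency), or as a JSON array of objects.
#'
#' @param candidates data frame of candidates.
#' @param path output path.
#' @param format `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_candidates <- function(candidates, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  preferred <- c("rank", "gene", "variant_id", "chrom", "pos", "ref", "alt",
                 "cosegregation", "bmd_gwas", "disease", "ko_phenotype",
                 "function_note", "evidence_score", "cadd_phred",
                 "sift_indel", "provean_indel", "maf")
  cols <- c(intersect(preferred, names(candidates)),
            setdiff(names(candidates), preferred))
  out <- as.data.frame(candidates)[, cols, drop = FALSE]
  if (format == "tsv") {
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE, na = ".")
  } else {
    jsonlite::write_json(out, path, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA, na = "null", pretty = TRUE)
  }
  invisible(path)
}
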