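# Independent brute-force oracles and fixture builders used across tests.
# The oracles iterate samples and pairs naively and share no code with the
# set-based implementations they check.

# One-row annotated variant with passing defaults, overridable per field.
make_variant <- function(variant_id = "v1", chrom = "S1", pos = 1000L,
                         ref = "A", alt = "G", gene = paste0("G_", variant_id),
                         region_class = "coding", consequence_class = "missense",
                         splice_affecting = NA, maf = 1e-4, cadd_phred = 25,
                         sift_indel = NA_character_,
                         provean_indel = NA_character_) {
  annotated_variants(data.frame(
    chrom = chrom, pos = pos, ref = ref, alt = alt, gene = gene,
    region_class = region_class, consequence_class = consequence_class,
    splice_affecting = splice_affecting, maf = maf, cadd_phred = cadd_phred,
    sift_indel = sift_indel, provean_indel = provean_indel,
    variant_id = variant_id, stringsAsFactors = FALSE))
}

bind_variants <- function(...) {
  out <- do.call(rbind, lapply(list(...), as.data.frame))
  annotated_variants(out)
}

# Flat pedigree of unrelated founders with given affection labels;
# proband = first affected.
flat_pedigree <- function(affected_flags, ids = paste0("S", seq_along(affected_flags))) {
  pedigree(data.frame(
    family_id = "F", individual_id = ids, father_id = "0", mother_id = "0",
    sex = "unknown",
    affected = ifelse(affected_flags, "affected", "unaffected"),
    z_ls = NA_real_, z_fn = NA_real_, stringsAsFactors = FALSE),
    proband_id = ids[which(affected_flags)[1]])
}

# Random instance: dosage matrix over a flat pedigree, no missing calls.
random_instance <- function(n_samples, n_variants) {
  aff <- rep(FALSE, n_samples)
  aff[sample(n_samples, sample(2:max(2, ceiling(n_samples / 2)), 1))] <- TRUE
  ped <- flat_pedigree(aff)
  gm <- matrix(sample(0:2, n_samples * n_variants, replace = TRUE,
                      prob = c(0.7, 0.25, 0.05)),
               nrow = n_variants,
               dimnames = list(paste0("v", seq_len(n_variants)),
                               ped$individual_id))
  list(ped = ped, genotypes = gm)
}

# Naive per-sample presence: proband carries, no unaffected carries.
brute_dominant <- function(gm, ped) {
  pro <- proband_id(ped)
  out <- logical(nrow(gm))
  for (i in seq_len(nrow(gm))) {
    ok <- gm[i, pro] >= 1
    for (u in unaffected_ids(ped)) if (gm[i, u] >= 1) ok <- FALSE
    out[i] <- ok
  }
  setNames(out, rownames(gm))
}

# Naive partition: map cell key -> variant ids by iterating samples.
brute_partition <- function(survivor_ids, gm, ped) {
  cells <- list()
  for (vid in survivor_ids) {
    carr <- character(0)
    for (s in affected_ids(ped)) if (gm[vid, s] >= 1) carr <- c(carr, s)
    key <- paste(sort(carr), collapse = ",")
    cells[[key]] <- c(cells[[key]], vid)
  }
  cells
}

# Naive O(n^2) pair enumeration over survivors.
brute_pairs <- function(survivor_ids, gm, ped) {
  aff <- sort(affected_ids(ped))
  carriers <- lapply(survivor_ids, function(vid) {
    sort(intersect(colnames(gm)[gm[vid, ] >= 1], aff))
  })
  names(carriers) <- survivor_ids
  pairs <- character(0)
  n <- length(survivor_ids)
  if (n >= 2) {
    for (i in 1:(n - 1)) {
      for (j in (i + 1):n) {
        a <- carriers[[i]]; b <- carriers[[j]]
        if (setequal(union(a, b), aff) && !setequal(a, aff) && !setequal(b, aff)) {
          pairs <- c(pairs, paste(sort(c(survivor_ids[i], survivor_ids[j])),
                                  collapse = "+"))
        }
      }
    }
  }
  sort(pairs)
}

fixture_path <- function(file) system.file("extdata", file, package = "hbmseg")
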