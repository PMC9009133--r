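Package: hbmseg
Title: Family-Based Rare-Variant Filtering and Additive-Pair Detection
    for High Bone Mineral Density Pedigrees
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis workflow for prioritizing rare coding variants in a
    pedigree segregating a high bone mineral density (HBM) phenotype under
    an autosomal dominant hypothesis. Quantifies the BMD phenotype from DXA
    Z-scores, applies a dominant presence/absence filter followed by an
    annotation filter cascade (region and consequence class, population
    minor allele frequency, CADD phred score for SNVs, SIFT/PROVEAN indel
    predictions, gene-level missense constraint), partitions surviving
    variants by the subset of affected carriers, detects additive
    two-locus candidate pairs whose carrier sets jointly cover all
    affected members, and ranks candidates by gene-level functional
    evidence. Includes a gene-dropping simulator that generates
    pedigree-consistent multi-sample VCFs with planted variants and a
    truth table, so every pipeline stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
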