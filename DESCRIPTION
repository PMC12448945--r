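Package: divscan
Title: Windowed Genomic Diversity, Homozygosity and Divergence Hotspot Scans
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Window-based comparative genome scans for a multi-species cohort
    sharing one reference coordinate frame: per-site genotype filtering and
    repeat masking, non-overlapping heterozygosity windows with
    chromosome-normalized values, run-of-homozygosity detection with FROH
    length-class decomposition, windowed interspecific genetic distance from
    pairwise alignment tracks, joint diversity/divergence hotspot calling with
    cross-species consensus, gene density and multicopy gene-family enrichment
    (Fisher exact test with Benjamini-Hochberg correction), and
    macro/microchromosome contrasts. Includes a seeded synthetic-cohort
    generator with a machine-readable ground-truth ledger for end-to-end
    validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    BiocGenerics,
    data.table (>= 1.14),
    IRanges,
    jsonlite,
    rtracklayer,
    S4Vectors,
    stats,
    utils,
    vcfR,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
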