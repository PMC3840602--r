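Package: starrrt
Title: Short Tandem Repeats in Gene Regulatory Regions
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects and ingests short tandem repeats (STRs, period 1-9 bp),
    maps them to strand-aware windows around transcription start sites
    (2 kb upstream to 1 kb downstream), and builds a 30-column annotation
    table of high-purity regulatory-region repeats. Includes per-base
    TSS-relative density, period-decomposition and base-composition
    profiling with LOWESS smoothing, CpG-island stratification,
    construction of exonic and high-density-intron comparison gene sets,
    hypergeometric over-representation tests with Benjamini-Hochberg
    correction and a majority-consensus reporting rule, and a synthetic
    genome simulator with planted repeats for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
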