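Package: adaptoscan
Title: Recurrent-Mutation Scans and Fitness Statistics for Microbial
    Experimental Evolution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Downstream analysis of microbial experimental-evolution
    sequencing and growth data. Identifies putatively adaptive genes and
    noncoding regions by a length-proportional randomization test with
    Bonferroni correction (with an exact binomial oracle mode), compares
    substitution-class counts against mutation-spectrum-based neutral
    expectations, estimates maximum growth rates and relative fitness
    from optical-density time series, and quantifies the repeatability
    of adaptation across environments (Dice similarity, per-gene
    contributions, cross-contamination diagnostics). Ships a synthetic
    data generator (genome, variant tables, plate layouts, growth
    curves) with a machine-readable truth ledger so the whole pipeline
    is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    methods,
    GenomicRanges,
    IRanges,
    S4Vectors,
    dplyr,
    jsonlite,
    rlang,
    rtracklayer,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
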