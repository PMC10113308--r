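Package: triomics
Title: Expression and Methylation Level Dominance Analysis in Parent-Hybrid Trios
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multi-omics dominance analysis for parent-parent-hybrid trios.
    Classifies differentially expressed genes, small-RNA clusters and
    differentially methylated regions into twelve dominance categories
    (additive, maternal/paternal dominant, transgressive) from replicate-level
    pairwise t-tests and Tukey HSD ranking; calls differentially methylated
    regions from binned cytosine reports with a two-proportion score test;
    detects CpG islands, coverage-based copy-number variants and 500-kbp
    segmental expression bias; and integrates expression with methylation
    (epialleles, flank association tests, Kendall correlation). A synthetic
    trio-data generator with machine-readable planted truth makes every stage
    verifiable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    yaml,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    rtracklayer,
    S4Vectors,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    jsonlite,
    optparse,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
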