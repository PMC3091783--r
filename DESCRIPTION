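Package: dister
Title: Operon Map Inference for Reduced Bacterial Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers bacterial transcription units (operons) from gene
    coordinates and Rho-independent terminator predictions with a naive
    Bayes classifier over adjacent same-strand gene pairs (intergenic
    distance binned in 10-bp intervals, terminator evidence, geometric
    transcription-unit-length prior), assembles genome-wide operon maps,
    validates maps against expression data with a length-preserving
    permutation ANOVA, and compares operon maps across genomes
    (five-class transcription-unit typing, ancestral gene pairs and
    fragments, coding-sequence length evolution). Includes a seeded
    synthetic-data generator with an analytic Bayes-optimal oracle for
    benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml,
    rtracklayer,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
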