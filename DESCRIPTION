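Package: trftracer
Title: Tracing Alien tRNA Fragments in Co-Culture Small RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for following bacterial tRNA-derived fragments (tRFs) across
    species boundaries in co-culture small RNA sequencing experiments.
    Implements dual-genome read classification with a bounded number of
    mismatches, marker 12-mer collection for tracing individual tRFs with
    positional profiling of read 5'- and 3'-ends, detection of circularly
    permuted reads (rotations of contiguous genomic segments) with ligation
    site reporting, and the derived quantities used in such studies:
    penetration efficiency, spike-in based concentration estimation,
    permutation frequency, replicate aggregation with standard errors,
    two-group tests with Bonferroni correction, and growth-curve areas.
    A synthetic-data generator produces toy genomes and read sets with known
    ground truth so every stage of the pipeline can be verified end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    S4Vectors,
    ggplot2,
    pracma,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
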