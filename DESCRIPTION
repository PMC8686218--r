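Package: epigep
Title: Two-Stage Detection of Epistatic SNP Interactions by Gene
    Expression Programming
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Detects k-locus epistatic interactions in case-control
    genome-wide association data with a two-stage procedure: a Gene
    Expression Programming screening stage using tailor-made chromosomes,
    adjacent and multi-gene mutation operators, fuzzy adaptive control of
    genetic manipulation rates and a K2 Bayesian-network fitness score,
    followed by a chi-square cleaning stage.  Includes a penetrance-table
    simulator of two-locus disease models under Hardy-Weinberg
    equilibrium with a built-in registry of 22 epistasis models, and
    power/recall/precision/F1 benchmarking utilities.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
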