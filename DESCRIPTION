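Package: netstab
Title: Stability of Microbial Co-Occurrence Networks from Count Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end toolkit for asking whether a microbial community is
    stable and what keeps it so, starting from a sample-by-taxon count table.
    Implements alpha/beta diversity with ordination and permutation group tests,
    phylogenetic (betaNTI) and taxonomic (Raup-Crick) null models with the
    five-process partition of community assembly, signed Spearman co-occurrence
    networks with module detection and Zi-Pi node roles, network stability
    metrics (secondary-extinction robustness, efficiency-based vulnerability,
    positive/negative cohesion), keystone-removal tests, ensemble-regression
    keystone importance, and a standardized linear path model of environmental
    drivers of stability. Ships a synthetic-data generator with recorded ground
    truth so the whole pipeline is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    randomForest,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vegan,
    withr
LinkingTo:
    Rcpp
Suggests:
    picante,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
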