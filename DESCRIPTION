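Package: dbht
Title: Directed Bubble Hierarchical Tree Clustering on Planar Filtered Graphs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Deterministic, parameter-free extraction of discrete clusters and
    a full hierarchical organization from a similarity matrix. Builds the
    Planar Maximally Filtered Graph (PMFG) by greedy edge insertion under a
    left-right planarity test, decomposes it into bubbles at separating
    3-cliques, directs the resulting bubble tree by edge-weight flows,
    anchors discrete clusters at converging bubbles, and assembles a
    three-level (intra-bubble, intra-cluster, inter-cluster) complete-linkage
    dendrogram over all elements. Includes multivariate Gaussian and
    log-normal block-correlation benchmark generators with configurable noise
    families, adjusted Rand index validation, a correlation-gap statistic,
    and a two-way (samples by genes) clustering driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    stats,
    utils,
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    jsonlite,
    readr,
    ape,
    mclust,
    generics
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
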