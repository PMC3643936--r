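Package: congru
Title: Module Discovery and Cross-Network Congruence in Multilayer
    Interaction Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Multi-resolution discovery of functional modules in molecular
    interaction networks and cross-network congruence analysis.  Builds
    weighted co-regulation layers from treatment significance calls,
    integrates layers into combined and common-gene networks, partitions
    each network over a planned range of resolutions with a balanced k-way
    partitioner, extracts and validates cohesive subgraphs by a path-length
    t-test, scores gene-set intersections between subgraphs of different
    networks (hypergeometric test, Matthews correlation coefficient, FDR,
    best and reciprocal best hits), and quantifies Gene Ontology coverage,
    co-enrichment and annotation-randomization controls.  Includes a
    planted-module synthetic benchmark generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    Matrix,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
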