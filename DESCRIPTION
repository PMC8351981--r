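Package: plcdm
Title: Seed-Centric Local Community Detection in Multilayer Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects the local community around a seed node in a multilayer
    (multiplex) network using a biased random walk with random restart. The
    walker favours neighbours that share many common neighbours with the
    current node and edges that recur across layers, switches layers in
    proportion to the Jaccard similarity of a node's per-layer
    neighbourhoods, and scores nodes by visit counts; the community is the
    set of nodes whose z-scored visit count is positive. Includes
    planted-partition generators for modular single-layer graphs, a
    probabilistic multilayer simulator, an exact Markov-chain oracle for the
    walk, and a per-seed evaluation harness computing specificity,
    precision, recall, accuracy, F1, Matthews correlation, false discovery
    rate and normalized mutual information against ground-truth modules.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    optparse,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
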