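Package: mwnetdyn
Title: Dynamic Multilayer EEG Network Analysis and Mind-Wandering Detection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds two-layer weighted multiplex functional-connectivity
    networks from band-limited multichannel EEG (amplitude envelope
    correlation and imaginary phase-locking value layers), segments
    recordings at points of network-structure change, clusters segments
    into recurring multilayer network states via Louvain community
    detection on a centrality-similarity graph, computes state-sequence
    dynamics statistics with a frequency-matched permutation null, and
    detects mind-wandering per participant with a two-hidden-state
    discrete-observation hidden Markov model classifier under
    cross-validation. Includes a synthetic-data generator that plants
    amplitude- and phase-coupling motifs switching under condition-specific
    Markov dynamics, so that every stage is testable without real
    recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    signal,
    stats,
    utils,
    Rcpp,
    car
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    pROC,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
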