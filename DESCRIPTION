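Package: emograph
Title: Emotion Recognition from EEG Connectivity Graphs and Peripheral
    Physiology
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A pipeline for binary valence and arousal classification from
    multichannel physiological recordings. EEG functional connectivity is
    estimated per sliding window by pairwise mutual information, weighted
    graph-theory measures (efficiency, path length, transitivity,
    modularity, density, clustering, betweenness, strength) are extracted
    from the resulting networks, and fused by concatenation with twelve
    time-domain statistics per peripheral channel. Feature selection uses a
    genetic-algorithm wrapper scored by classifier accuracy; evaluation
    covers subject-dependent splits and leave-one-subject-out
    cross-validation with linear SVM, random forest, gradient boosting and
    a one-dimensional convolutional network, all implemented in the
    package. A seeded synthetic-data generator plants class-dependent EEG
    coupling and peripheral statistics so the full pipeline is testable
    without access to gated datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    rhdf5,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
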