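Package: broilerseq
Title: Sequential Pattern Mining of Broiler Chicken Behavior
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the temporal organisation of broiler chicken
    behaviour from ethogram-coded bout annotations. Converts time-stamped
    behaviour bouts into per-bird sequence databases of five-minute observation
    windows, mines frequent sequential patterns with a level-wise generalized
    sequential pattern (GSP) engine under a user-set minimum support, and
    summarises results as minimum-support sweep reports (newly reported maximal
    patterns per threshold level, size tallies, behaviour coverage). Includes a
    brute-force mining oracle for verification, a seeded semi-Markov flock
    simulator with condition presets for thermoneutral and heat-stress housing
    with and without environmental enrichment, and pattern-planting utilities
    for recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
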