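Package: bgcniche
Title: Phylogenetic Comparative Analysis of Biogeochemical Niche Evolution
Version: 0.1.0
Authors@R:
    person("Kai", "Moreland", email = "kai.moreland@posteo.net", role = c("aut", "cre"))
Description: Tools for studying the evolution of the biogeochemical niche --
    a species' characteristic leaf elemental composition (C, N, P, K, Ca, Mg)
    -- on a time-calibrated phylogeny. Implements Blomberg's K with a
    permutation null, maximum-likelihood fits of Brownian motion (single- and
    two-rate), Pagel's delta, and single- and two-optimum Ornstein-Uhlenbeck
    models compared by AICc, stepwise detection of optimum shifts under a
    penalized information criterion, phylogenetic generalized least squares
    with simultaneous Pagel's lambda estimation, life-form group descriptives
    with PCA, and simulators for trees, regimes, and traits under every fitted
    model so each stage can be validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
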