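Package: mbflex
Title: Analysis of Flexible Odor-Memory Recall in the Fly Mushroom Body
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for analysing calcium-imaging and behavioral experiments on
    odor-memory specificity in the Drosophila mushroom body. Provides
    trial-aligned fluorescence containers and delta-F-over-F quantification,
    transition-contrast scoring, a from-scratch logistic-regression population
    decoder with leave-one-out cross-validation and pulse-to-transition
    transfer protocols, circular-arena performance-index and
    upwind-displacement metrics, Wilcoxon testing with Bonferroni-Holm
    correction, and seeded synthetic-data generators (Kenyon-cell tensors,
    mushroom-body output neuron traces, connectome-style synapse counts, and
    arena trajectories) that emulate the statistical structure the analyses
    assume, so every stage can be tested against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
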