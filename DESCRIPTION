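Package: evoassembly
Title: Assembly Rules and Repeatability of Coevolving Bacterial Communities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of two- and three-species bacterial community
    composition time series from serial-dilution coevolution experiments.
    Provides compositional change and replicate-variability metrics with a
    Dirichlet random-community null, a permutation (shuffle) null for the
    repeatability of the maximally increasing species, the pairwise-to-trio
    assembly rule based on weighted geometric means of pair fractions with
    its accuracy score, growth-parameter extraction from plate-reader curves
    (time-to-threshold rate, end-of-cycle carrying capacity) with
    growth-based dominance predictions, and a generalized Lotka-Volterra
    serial-dilution simulator with parameter drift that generates synthetic
    community data with the same statistical structure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    ggplot2,
    generics,
    deSolve,
    zoo,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
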