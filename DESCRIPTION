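Package: foldphi
Title: Chevron-Plot Fitting and Phi-Value Analysis for Two- and
    Three-State Protein Folding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Kinetic and thermodynamic analysis of stopped-flow protein
    folding experiments in chemical denaturant. Fits chevron plots and
    initial/endpoint fluorescence amplitudes to the analytical solution of
    a two-state (U<->N) or on-pathway three-state (U<->I<->N) folding
    scheme with exponential denaturant dependence of every microscopic
    rate constant, fits equilibrium denaturation curves by the linear
    extrapolation method, and derives free energies, kinetic m-values,
    Tanford beta values, mutation-induced delta-delta-G values and
    phi-values for the intermediate and the rate-limiting transition
    state, with first-order (delta-method) error propagation throughout.
    Includes a seeded synthetic-data generator for kinetic traces,
    chevron datasets and equilibrium curves so the whole pipeline can be
    exercised and validated without instrument data.
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
    lhs,
    minpack.lm,
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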