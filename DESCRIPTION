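Package: nanogate
Title: Stochastic Gene-Network Modelling of Mouse Embryonic Stem Cell
    Pluripotency
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of a stochastic gene-regulatory-network
    model of mouse embryonic stem cell (mESC) pluripotency. The network couples
    the Oct4-Sox2 heterodimer, Nanog, Rex1 and FGF4/Erk signalling through Hill
    kinetics with multiplicative transcriptional noise, and gates an extrinsic
    differentiation signal by the Nanog level. The package provides deterministic
    fixed-point and bifurcation analysis, a compiled Euler-Maruyama integrator
    for single cells and populations, attractor-basin transition and
    residence-time statistics, differentiation experiments with a per-cell
    stochastic ramp of the Erk repression rate, calibration of a reference
    parameter set to distributional phenotype constraints, and generators for
    surrogate flow-cytometry and qRT-PCR observations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    mclust,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    knitr,
    lhs,
    nortest,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
VignetteBuilder: knitr
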