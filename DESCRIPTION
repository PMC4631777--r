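Package: spindlesim
Title: Stochastic Force-Balance Simulation and Analysis of Chromosome
    Congression in Fission Yeast
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A coarse-grained, one-dimensional force-balance model of the
    fission-yeast mitotic spindle with stochastic kinetochore-microtubule
    attachment and detachment, an optional length-dependent pulling-force
    prefactor emulating kinesin-8 activity, and a quantitative analysis
    toolkit for kinetochore and spindle-pole trajectories: spindle-axis
    projection, normalized centering distances, FFT and local-extrema
    oscillation metrics, inter-event drifts, anaphase lagging times,
    mis-segregation calls, and length-binned microtubule fluorescence
    profile statistics. Includes a synthetic-data generator so the whole
    analysis pipeline is testable without microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
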