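Package: bcrsurv
Title: Kinetic Modeling of Tonic and Antigen-Triggered BCR Survival Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modeling the survival of primary B cells as a balance
    between the tonic survival signal generated by free surface B-cell
    receptor (BCR) and the signal triggered by antigen-surrogate
    (anti-IgM) crosslinking. Provides the per-cell kinetic model (BCR
    decay, antibody binding kinetics with closed-form occupancy, and a
    thresholded survival-signal balance), fixed-step Runge-Kutta
    simulation of single cells and cohorts with a death-threshold rule,
    generators for synthetic flow-cytometry-like BCR distributions and
    noisy observation sets, and a two-stage estimation pipeline combining
    weighted least squares with a real-coded genetic algorithm (unimodal
    normal distribution crossover with minimal-generation-gap selection).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
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
    withr
LinkingTo: Rcpp
Suggests:
    deSolve,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
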