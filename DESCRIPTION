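Package: s1pk
Title: Population and Noncompartmental Pharmacokinetics of S-1 (Tegafur/5-FU) in Rats
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Simulation, noncompartmental analysis and population (nonlinear
    mixed-effects) estimation for the oral anticancer combination S-1 in rats.
    Implements a six-state linear parent-metabolite model for tegafur and its
    active metabolite 5-fluorouracil (5-FU) with first-order absorption, a gut
    and hepatic first-pass route into a 5-FU precursor, and two-compartment
    disposition for both analytes. Provides matrix-exponential and adaptive-ODE
    simulation, closed-form AUC and terminal-slope oracles, WinNonlin-style
    noncompartmental analysis (lambda-z selection, AUC, CL/F, Vz/F), an
    importance-sampling Monte Carlo parametric EM estimator with group
    covariate effects and log-normal between-subject variability, visual
    predictive checks and normalized prediction distribution errors, and a
    synthetic two-group rat study generator with LLOQ censoring so the whole
    pipeline is testable without animal data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    dplyr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    ggplot2,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
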