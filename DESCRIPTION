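Package: actinwaves
Title: Stochastic Actin-Wave Dynamics at Three Levels of Description
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of an excitable activator-inhibitor
    model of cortical actin waves on a one-dimensional periodic membrane
    slice, at three levels of description: the macroscopic deterministic
    reaction-diffusion equation, the mesoscopic chemical Langevin equation
    (a stochastic PDE with multiplicative reaction noise and conservative
    diffusion noise), and the microscopic stochastic simulation algorithm
    (well-mixed Gillespie and a spatial reaction-diffusion master equation).
    Includes background-state and Hopf-bifurcation analysis, Newton solvers
    for travelling- and standing-wave profiles with a phase condition, and
    kymograph event detection with ensemble statistics versus noise
    intensity.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    tibble,
    dplyr,
    tidyr,
    rlang,
    ggplot2,
    jsonlite,
    pracma,
    generics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr
Config/testthat/edition: 3
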