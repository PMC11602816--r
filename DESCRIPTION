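Package: mgrdme
Title: Multi-Grid Reaction-Diffusion Master Equation Modelling of Morphogen Gradients
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Compartment-based stochastic reaction-diffusion modelling with
    species-specific lattice resolutions (the multi-grid reaction-diffusion
    master equation, mgRDME), applied to morphogen gradient formation.
    Provides exact stationary solvers for first-order networks, a Gillespie
    stochastic simulation algorithm for both first-order conversion and
    second-order dimerization networks on dual-resolution lattices, a
    particle-based Brownian dynamics ground truth with the Doi (lambda-rho)
    bimolecular reaction, and error/cost multi-objective (Pareto) analysis
    over compartment sizes.
License: MIT
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    optparse,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
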