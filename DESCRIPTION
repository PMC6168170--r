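Package: epiland
Title: Probabilistic Landscapes and Transition States in Stochastic Models of Cell Differentiation
Version: 0.1.0
Authors@R: person("Epiland", "Maintainers", email = "maintainers@epiland.org", role = c("aut", "cre"))
Description: Tools to quantify Waddington-style epigenetic landscapes for stochastic
    models of cell differentiation. Implements two fully specified model systems (a
    two-dimensional bistable potential with an orthogonal curl component, and a
    four-gene Nanog/Oct4-Sox2/Fgf4/Gata6 birth-death network under external LIF
    control), exact Gillespie simulation, chemical Langevin and Euler-Maruyama
    integrators with time-varying parameter ramps, empirical probability landscapes
    (negative log density), deterministic fixed-point location with Jacobian
    eigenvalue classification and parameter sweeps, Freidlin-Wentzell minimum action
    paths in the differentiation and reprogramming directions, and ensemble-variance
    signatures of transitory landscapes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
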