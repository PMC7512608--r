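Package: latticegame
Title: Spatial Evolutionary Potential Games with Competing Ising and Potts Phases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and solver suite for multi-strategy evolutionary
    potential games on the periodic square lattice. Implements logit-rule
    (Glauber-type) Monte Carlo dynamics whose stationary state is the
    Boltzmann distribution over the configuration potential, exact
    enumeration oracles for tiny lattices, one-site (mean-field) and
    two-site (pair approximation) cluster-variation solvers of the
    thermodynamic potential, and transition analysis: order parameters,
    power-law fits of continuous order-disorder transitions, Binder-cumulant
    crossings, and location of entropy-driven first-order transitions
    between competing ordered phases. The canonical model is a five-strategy
    coordination game composed of an Ising pair and a three-state Potts
    triple of strategies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
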