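Package: steadyCME
Title: Direct Steady-State Probability Distributions for Stochastic
    Reaction Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Computes stationary probability distributions of mass-action
    stochastic reaction networks directly from the chemical master equation.
    The state space is truncated to a finite box in conservation-reduced
    coordinates, the sparse probability-flow generator is assembled, and the
    singular eigenproblem at eigenvalue zero is converted to a well-posed
    linear system anchored at the discrete state nearest the deterministic
    steady state. The box expands adaptively until the probability mass on
    its faces falls below a tolerance. Includes a Gillespie stochastic
    simulation reference, noise statistics (coefficient of variation, percent
    noise change, response classification), and parameter-screen drivers for
    ligand-receptor networks of BMP signaling with a secreted co-factor
    (Crossveinless-2) and with Type II receptor recruitment.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    deSolve,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
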