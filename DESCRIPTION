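Package: smolcrn
Title: Adaptive Smolyak Sparse Grids for Parametric Analysis of Reaction
    Network Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Dimension-adaptive Smolyak sparse-grid interpolation and
    quadrature on nested Clenshaw-Curtis nodes for global parametric
    analysis of mass-action chemical reaction network ODE models.
    Builds certified polynomial surrogate models over a full parameter
    box, computes moments and Bayesian posterior quantities (evidence,
    posterior expectations) by sparse quadrature, and provides
    first-order sensitivity, sloppiness (chi-square Hessian eigenvalue)
    and index-activation diagnostics, together with a Metropolis-Hastings
    MCMC baseline for comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    optparse,
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
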