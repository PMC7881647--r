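Package: spdeprev
Title: Bayesian Spatio-Temporal Geostatistical Prevalence Mapping for Cluster Surveys
Version: 0.1.0
Authors@R:
    person("spdeprev", "developers", email = "spdeprev@example.org", role = c("aut", "cre"))
Description: Model-based geostatistical analysis of cluster-survey prevalence
    data (DHS-style surveys with displaced coordinates). Implements a sparse
    Matern latent Gaussian field via the SPDE finite-element approximation on a
    triangulated mesh, a separable Kronecker space-time precision with AR1 or
    exchangeable time knots, a constrained logit-binomial hierarchical model
    fitted by blocked MCMC, DIC/MPL variable selection with all-subsets search,
    k-fold cross-validation, and high-resolution risk mapping with
    population-adjusted administrative aggregation. Includes a synthetic
    DHS-like survey generator with known ground truth so the full pipeline is
    testable without restricted microdata.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
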