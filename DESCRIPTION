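Package: sgdege
Title: Stochastic Gradient Descent with Estimated Global Errors in Cerebellar Circuits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Rate-model simulators for perturbation-based cerebellar learning.
    Implements stochastic gradient descent with estimated global errors (SGDEGE):
    a full cerebellar microzone network in which spontaneous climbing-fibre
    perturbations of Purkinje cell firing are converted into weight updates by
    comparing the global movement error against an adaptively learned inhibitory
    cancellation at the inferior olive; a Marr-Albus-Ito baseline showing why a
    single broadcast error signal cannot optimise many output variables; a reduced
    single-cell phase-plane model with corridor geometry, analytic fixed point and
    convergence conditions; and an analog perceptron variant with delta-rule
    comparison and empirical storage-capacity scanning. Simulations return tidy
    per-trial trajectories with broom-style accessors and ggplot2 plotting.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
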