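Package: npndiff
Title: Differential Network Testing for Nonparanormal Graphical Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects differential edges between two or more gene networks
    modelled as nonparanormal (Gaussian copula) graphical models, with
    false discovery rate control. Latent Gaussian data are imputed through
    a Winsorized empirical-CDF transform, per-class partial correlations
    are estimated by node-wise lasso or Dantzig-selector regression with a
    bias-corrected residual statistic, class differences are combined into
    a sum-squared statistic mapped to the normal scale through a weighted
    chi-square distribution, and differential edges are called with an
    empirically corrected large-scale FDR threshold. Includes a simulation
    harness (band and Erdős–Rényi precision models with sign-flipped
    differential edges) and median/variance-matching batch correction for
    expression matrices.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    pracma,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    readr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    optparse,
    withr
Config/testthat/edition: 3
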