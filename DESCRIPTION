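Package: autoshift
Title: Detecting Long-Lived Autocorrelation Changes in Multivariate Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for screening multivariate time series for long-lived
    changes in autodependency (lag-1 autocorrelation). Implements KCP-AR,
    a kernel change point method applied to running autocorrelations with
    a variance-drop permutation test and a penalty grid search for choosing
    the number of change points, and a regime-switching AR(1) model fitted
    by maximum likelihood with AIC/BIC regime selection. Includes a
    phase-structured VAR(1) simulator and an evaluation harness (Rand
    Index, power and type-I error studies) for comparing both detectors.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    jsonlite,
    ggplot2,
    generics
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
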