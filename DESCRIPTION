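Package: deplsa
Title: Local Similarity Analysis for Dependent Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Local similarity analysis (LSA) detects associations between
    time series that hold only over a subinterval, possibly with a time
    delay, as is common for OTU abundance profiles in longitudinal
    microbiome studies. Classical theoretical and permutation p-values for
    the local similarity score assume independent observations and become
    grossly anti-conservative when the series are autocorrelated. This
    package provides significance approximations that remain valid for
    dependent (weakly stationary) series: a data-driven test that plugs a
    Bartlett-kernel long-run variance estimate with Andrews' AR(1)
    automatic bandwidth into the LS-score tail distribution, and a
    residual-based test that whitens each series with an AIC-selected
    AR/ARMA fit before applying the i.i.d. theory. Also included are the
    classical baselines (theoretical LSA, permutation, Pearson and
    Spearman correlation), simulators for the null and locally associated
    alternative models used to study size and power, a Monte-Carlo harness
    for type-I error and power experiments, and an all-pairs abundance
    table pipeline with prevalence filtering, linear interpolation,
    Ljung-Box autocorrelation screening and false discovery rate control.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    generics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
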