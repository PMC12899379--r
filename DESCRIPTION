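Package: fbam
Title: Frequency Band Analysis of Multiple Stationary Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Data-adaptive discovery of frequency band summary measures for
    collections of stationary time series, with simultaneous identification of
    subpopulations with distinct power spectra. Replicate-specific spectra are
    estimated with sine-taper multitaper estimators; band partitions and
    subpopulation memberships are found by minimizing a least-squares objective
    with an island-model genetic algorithm, and the numbers of bands and
    subpopulations are selected with cluster-validation style similarity
    criteria. Includes simulators for piecewise-smooth and autoregressive
    spectral populations and tools to score recovered structure against ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    mclust,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
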