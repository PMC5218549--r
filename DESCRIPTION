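Package: sarprobit
Title: Bayesian Spatial Autoregressive Probit Models for Landowner Survey Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for spatial binary-choice analysis of owner-level survey
    data, motivated by studies of family forest owners' willingness to
    harvest timber. Builds row-standardized spatial weight matrices from
    parcel coordinates by Delaunay triangulation, fits standard probit
    models by maximum likelihood, estimates Bayesian spatial autoregressive
    (SAR) probit models by Markov chain Monte Carlo with a griddy Gibbs
    step for the spatial dependence parameter, and decomposes covariate
    impacts into average direct, indirect (spillover), and total marginal
    effects. A synthetic-data generator reproduces the covariate and
    spatial-dependence structure the models assume so every stage can be
    exercised without confidential survey data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    deldir,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    methods,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    readxl,
    geosphere,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
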