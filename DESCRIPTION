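Package: martram
Title: Marginally Interpretable Transformation Models for Clustered Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits marginally interpretable linear transformation models for
    clustered and longitudinal observations. The joint distribution couples
    linear transformation model margins (probit, logit, cloglog or loglog
    scale; Bernstein-polynomial, linear, log-linear or discrete baseline
    transformations) through a Gaussian copula whose structured latent
    covariance is induced by random-intercept or random-intercept/slope
    designs. Exact likelihoods are available for binary, ordinal and
    interval-censored responses via dimension-reduced multivariate normal
    rectangle probabilities, and an approximate log-density likelihood with
    analytic scores for continuous responses. Closed-form marginal
    distributions, shrunken marginal effects, probabilistic indices and
    simulation-based confidence intervals are provided, together with a
    synthetic-data generator and a simulation-study harness for evaluating
    coverage, interval width and mean squared error of marginal effects.
License: GPL (>= 3)
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    statmod,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    knitr,
    rmarkdown,
    lme4,
    numDeriv,
    mvtnorm,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
VignetteBuilder: knitr
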