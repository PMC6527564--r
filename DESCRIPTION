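Package: socialnoise
Title: Social Noise and Volatility Learning with Hierarchical Gaussian Filters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how perceptual uncertainty induced by
    emotionally incongruent feedback ("social noise") degrades learning in
    volatile probabilistic association tasks. Generates task schedules and
    synthetic cohorts of model-driven agents; filters trial sequences through
    four learning models (three-level binary hierarchical Gaussian filter,
    its social-noise extension HGF-S, Rescorla-Wagner, and Sutton K1); fits
    model parameters by MAP with Laplace-approximate log model evidence;
    performs random-effects Bayesian model selection with exceedance and
    protected exceedance probabilities; and computes the SN_d
    decision-change interaction statistic, its group tests, and
    tau-perturbation simulation experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
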