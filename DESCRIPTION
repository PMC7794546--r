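Package: spectratune
Title: Automated Hyperparameter Optimisation of 1D Convolutional Networks
    for Spectroscopic Regression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and tuning one-dimensional convolutional
    neural networks that predict soil properties (e.g. soil organic carbon)
    from visible-near-infrared reflectance spectra. Provides a
    tree-structured, mixed-type hyperparameter search space covering
    architecture, preprocessing-channel and training choices; a Tree-
    structured Parzen Estimator (TPE) Bayesian optimiser and a random-search
    baseline minimising k-fold cross-validated RMSE; multi-channel spectral
    preprocessing (reflectance, absorbance, derivatives, standard normal
    variate); deterministic architecture shape arithmetic; an in-package
    network training engine with early stopping; functional-ANOVA
    hyperparameter importance from search histories; and a synthetic
    vis-NIR spectra generator so the whole pipeline is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
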