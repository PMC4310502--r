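Package: inertia
Title: Centering and Bias in Multilevel Autoregressive Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how the centering of a lagged level-1
    predictor affects estimation in two-level autoregressive ("inertia")
    models of intensive longitudinal data. Provides simulators for the
    standard two-level model with distinct within- and between-cluster
    slopes and for the multilevel AR(1) model with random means and random
    autoregressive parameters (optionally driven by a level-2 covariate);
    lagging and centering transforms (no centering, grand-mean centering,
    and cluster-mean centering with sample, empirical-Bayes, or true
    cluster means); closed-form between- and within-cluster OLS
    estimators; linear mixed-model fitting via 'lme4' with broom-style
    tidiers; Monte-Carlo drivers that summarise bias, Monte-Carlo error
    and confidence-interval coverage across replicated
    simulate-center-fit pipelines; and analytic plus simulation oracles
    for the O(1/T) downward (Nickell-type) bias of the demeaned AR(1)
    slope estimator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lme4,
    purrr,
    readr,
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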