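Package: balanceAD
Title: AI-Based Balance Assessment from Force-Platform Stabilometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A complete pipeline for anomaly-detection-based balance
    assessment from raw force-platform recordings. Computes center-of-pressure
    (CoP) trajectories from six-channel force/moment signals, extracts the
    standard stabilometric summaries (95% prediction ellipse area, mean sway
    velocity, spectral median frequency) under the four Romberg-style
    conditions (firm/foam surface crossed with eyes open/closed), assembles a
    19-variable socio-anthropometric and postural feature matrix, trains a
    dense 19-20-20-19 feed-forward network with permuted-participant targets
    using Bayesian-regularization Levenberg-Marquardt, scores each participant
    by the agreement (R-squared) between their simulated and measured
    profiles, forms percentile subgroups, and compares subgroups with
    ANOVA/Bonferroni statistics and multiplication-factor summaries. Includes
    a fully seeded synthetic-cohort simulator so the entire pipeline is
    testable without access to laboratory recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    car,
    jsonlite,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
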