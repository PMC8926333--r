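Package: fairconn
Title: Fairness Auditing for Connectome-Based Behavioral Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Audits cross-population generalization of connectome-based
    behavioral prediction models. Provides frame censoring and Fisher-z
    resting-state functional connectivity computation, Hungarian matched-pair
    test-set construction with family- and site-aware cross-validation splits,
    kernel and linear ridge regression with training-side confound control,
    group-wise accuracy and bias metrics (predictive coefficient of
    determination with pooled training variance, Pearson accuracy, prediction
    shift), permutation and block-permutation inference with false discovery
    rate control, training-population composition experiments, and
    Haufe-style recovery of brain-behavior association patterns. A synthetic
    multi-group, multi-site data generator with known ground-truth edge-weight
    patterns makes every stage testable end to end.
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
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
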