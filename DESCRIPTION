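Package: pvblearn
Title: Asymmetric Reinforcement Learning and Provariance Bias in a Magnitude Learning Task
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a two-armed card-deck magnitude learning task in which
    deck outcome distributions differ in mean and variance, models choice
    behavior with a Rescorla-Wagner learner carrying separate learning rates
    for positive and negative prediction errors, and provides per-subject
    maximum-likelihood fitting with BIC model comparison, parameter and model
    recovery diagnostics, behavioral statistics (provariance bias, block
    accuracies, exclusion rules, anxiety-depression trait composites), and
    export of model-derived prediction-error regressors as FSL 3-column event
    files for model-based fMRI designs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    lhs,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2,
    knitr,
    rmarkdown
Config/testthat/edition: 3
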