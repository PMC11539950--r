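Package: validiv
Title: Prediction-Validity Instrumental Variable Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Instrumental-variable estimation with an empirical validity check
    based on prediction rather than correlation. Fits constrained two-stage and
    joint one-stage estimators for linear and general additive (polynomial /
    transformed feature) IV models, where the second stage is required not to
    leave remainders that the instrument can predict better than a model that is
    identically zero. Includes seeded synthetic data generators for valid and
    non-instrument designs with correlated confounding errors, Monte-Carlo
    experiment drivers (confusion matrices, misspecification detection,
    robustness of the causal-effect estimate), and a property suite verifying
    the feasibility taxonomy of the constrained problem across model classes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    jsonlite,
    ggplot2,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
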