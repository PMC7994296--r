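Package: fcdyn
Title: Time-Varying Functional Connectivity States and Kernel-Based Trait Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify how much of individual behavioural variability is
    carried by time-varying functional connectivity (FC), time-averaged FC, and
    structural brain features. Fits group-level hidden Markov models whose states
    are zero-mean Gaussians with full covariance (FC states), with mean- and
    variance-only control variants, by variational Bayesian inference; derives
    subject-specific models by dual estimation; reduces every representation to a
    subject-by-subject distance matrix via symmetric Kullback-Leibler divergence
    or Euclidean distance; predicts traits with Gaussian-kernel ridge regression
    under family-respecting nested cross-validation, with cross-validated
    structural deconfounding and motion confound handling; and compares
    representations with permutation tests, bootstrap representation-similarity
    analysis, and split-half reproducibility. Includes a synthetic cohort
    generator with controlled trait variance attribution so the whole pipeline is
    testable without restricted data.
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
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
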