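Package: tastemix
Title: Analysis of Taste-Mixture Two-Alternative-Choice Ephys Sessions and
    Data-Constrained Recurrent Network Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for behavioral-electrophysiology sessions from a binary
    taste-mixture two-alternative-choice task: event-warped firing-rate
    tensors and PSTHs, per-unit auROC discrimination time courses,
    responsivity/selectivity screens, class-balanced leave-one-out
    nearest-centroid decoding with binomial significance thresholds, demixed
    PCA with missing-condition regression imputation, tuning-curve shape
    classification (linear vs step templates, extra-sum-of-squares F-tests,
    step-perception vs step-choice disambiguation via error trials),
    4-parameter logistic psychometrics, and a data-constrained rate recurrent
    network trained by backpropagation-through-time to reproduce session
    PSTHs and choices, with input-noise calibration and virtual ablation of
    functional unit classes. Includes a synthetic-session generator with
    known ground-truth coding types for end-to-end validation.
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
    withr
Suggests:
    MASS,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
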