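Package: combosens
Title: Dose-Specific Prediction of Drug Combination Sensitivity in Cancer
    Cell Lines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts the relative growth inhibition of cancer cell lines
    treated with one or two drugs at explicit concentrations, instead of
    aggregated synergy scores. Provides preprocessing for combination-screen
    tables, principal-component cell-line features with four drug and
    concentration encodings, cell-blind model training and cross-validation,
    reconstruction of three-parameter logistic dose-response curves and
    dose-response matrices from predictions, sensitivity measures including
    IC50/IC75/IC90 and the (combination) CMax viability, per-cell-line
    treatment prioritization, and a synthetic screen generator with known
    ground truth for end-to-end validation.
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
    glmnet,
    minpack.lm,
    nnet,
    pracma,
    purrr,
    ranger,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
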