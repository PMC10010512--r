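Package: pdscreen
Title: Picture-Description Speech and Language Screening for MCI Subtypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for screening mild cognitive impairment (MCI)
    subtypes from picture-description responses. Scores content-unit, lexical
    and length features from POS-tagged transcripts; quantile normalizes
    acoustic and language feature matrices; builds all within-modality
    pairwise contrasts; runs age- and gender-adjusted logistic association
    screens with Benjamini-Yekutieli false discovery rates; evaluates
    per-feature ridge classifiers with repeated cross-validation and
    specificity-constrained thresholds; and fits elastic-net and penalized
    multinomial risk scores with split-aware low-rank imputation of missing
    vocal-tremor features. Includes a synthetic cohort generator emulating
    the statistical structure the analysis assumes, so the full pipeline is
    testable without participant-level data.
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
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
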