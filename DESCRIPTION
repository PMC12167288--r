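Package: npdepth
Title: Combined Microvessel and FDG-PET Risk Categorisation for Invasion
    Depth in Superficial Esophageal Cancer
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for evaluating preoperative prediction of deep submucosal
    invasion (pT1b-SM2 or deeper) in superficial esophageal squamous cell
    carcinoma from Japan Esophageal Society (JES) type-B microvessel
    classification under magnifying narrow-band imaging and the maximum
    standardised uptake value (SUVmax) on FDG-PET. Implements the combined
    "N-P" risk category (type B1, or B2 with low uptake, is low-risk; B2 with
    SUVmax at or above a cutoff, or B3, is high-risk), ROC construction with
    Youden-index cutoff selection and a DeLong confidence interval for the
    c-statistic, contingency-table diagnostic performance with exact binomial
    confidence intervals, Fisher exact and rank-sum comparisons, logistic
    adjustment for lesion morphology, a calibrated synthetic lesion-cohort
    generator, and an end-to-end analysis report.
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
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
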