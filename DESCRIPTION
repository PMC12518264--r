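Package: mohi
Title: Multidimensional Oral Health Indicator Construction and Cohort Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores the Oral Health Value Scale (OHVS, 12 items), the Oral
    Health Impact Profile short form (OHIP-14) and the Decayed/Missing/Filled
    Teeth (DMFT) caries index from raw item- and tooth-level records, combines
    them into the Multidimensional Oral Health indicator (MOHi) -- an equally
    weighted sum of the three normalized scores on a 0-3 scale, higher meaning
    more degraded oral health -- and runs the surrounding cohort analysis:
    distribution descriptives, two-group and one-way ANOVA contrasts with
    homogeneous-subset letters, stepwise logistic risk modelling of a degraded
    oral-health outcome (MOHi >= 1.5) with Nagelkerke R-squared, classification
    accuracy and ROC/AUC, and an alternative high-caries (DMFT >= 14) model.
    Includes a latent-severity synthetic cohort generator for testing every
    analysis stage without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    broom,
    dplyr,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    e1071,
    jsonlite,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
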