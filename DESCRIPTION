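Package: frailtycompare
Title: Compare Deficit-Accumulation and Phenotypic Frailty Measures in Cohort Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to construct a five-criterion phenotypic frailty score and a
    34-item deficit-accumulation frailty index from questionnaire-style cohort
    tables of older women, place the two instruments on a common footing using
    three stratification strategies (per one-fifth increments, density-overlap
    trichotomization, and predicted fall-risk grouping), fit logistic and Cox
    proportional-hazards outcome models for falls, fractures and death, and
    compare predictive accuracy with paired discrimination statistics (DeLong
    tests for correlated areas under the curve, Harrell concordance with a
    paired bootstrap contrast, Hosmer-Lemeshow calibration, and tie-corrected
    Spearman agreement).  Includes a latent-trait synthetic cohort generator
    so every stage of the pipeline can be exercised against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
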