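Package: staturecast
Title: Adult and Stage Height Prediction for Children from Growth Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts the adult height and intermediate ("stage") heights of
    children and adolescents from routine growth records (age, bone age,
    height, weight).  A per-sex multilayer perceptron trained under a banded
    squared loss (residuals within a tolerance band contribute nothing)
    regresses adult height on a six-feature encoding of one measurement; a
    population mean growth curve is fitted to a 0 SD height-for-age reference
    by polynomial least squares; and a per-child three-parameter registration
    of that curve (tempo, phase, amplitude) yields height predictions at any
    target age.  Includes classical baselines (mid-parental genetic height,
    Bayley-Pinneau percentage method), a seeded longitudinal cohort
    simulator, and the usual error metrics (MAE, RMSE, within-k-cm accuracy,
    boxplot summaries).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
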