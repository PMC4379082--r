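Package: uhtape
Title: Color-Coded Uterine Height Tapes for Gestational Age Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Designs tri-zone (color-coded) uterine-height measuring tapes
    from per-week symphysis-fundal height percentile charts and evaluates
    their diagnostic accuracy for identifying preterm-range pregnancies.
    Provides a synthetic cohort generator for paired-operator calibration
    data and stratified evaluation cohorts, Bland-Altman operator
    agreement, per-week growth charts (mean, SD, P10/P50/P90), tape
    construction from percentile cut-offs at 24 and 36 completed weeks,
    zone classification, cross-tabulation against ultrasound-dated
    gestational-age bands, sensitivity and specificity with binomial
    confidence intervals, empirical ROC curves with trapezoidal AUC over
    discrete tape operating points, prevalence-conditioned predictive
    projections, and a reproduction of a published multi-country
    evaluation from embedded cross-tabulation fixtures.
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
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
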