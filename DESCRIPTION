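Package: coretemp
Title: Heart-Rate-Based Core Temperature Estimation and Validation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimates core body temperature minute-by-minute from sequential
    heart-rate observations with a scalar extended Kalman filter whose
    observation model is a sigmoid heart-rate-versus-temperature curve, and
    validates the estimates with the agreement statistics used in exercise
    thermophysiology: repeated-measures Bland-Altman limits of agreement,
    participant- and duration-weighted root mean square error, Pearson
    correlation, per-athlete peak analysis, subgroup ANOVA, and a
    sensitivity/specificity threshold sweep with qualitative grading.
    Includes a seeded synthetic-cohort generator emulating incremental
    heat-stress exercise tests, preprocessing of raw wearable streams
    (outlier removal, minute averaging, gap interpolation), and a
    reproducible end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    utils,
    tools,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
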