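Package: eplscore
Title: Points-Based Risk Scoring for Early Pregnancy Loss After IVF-ET
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Derivation, application and validation of an integer
    points-based scoring system (Sullivan/Framingham style) that predicts
    early pregnancy loss from first-trimester ultrasound biometry and
    maternal demographics after in vitro fertilization with embryo
    transfer. Provides the published six-factor scoring system as a
    fixture, a synthetic-cohort generator with group-conditional and
    logistic-generative modes, logistic model fitting with backward
    stepwise screening, point-table derivation from fitted coefficients,
    per-cutoff diagnostic performance tables (sensitivity, specificity,
    predictive values, accuracy), rank-based AUC, and an end-to-end
    derivation pipeline with a temporal train/verify split.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
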