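Package: twincens
Title: Censored-FIML Twin Models for Gene-by-SES Analysis of Educational
    Achievement
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Classical twin-design analysis of right-censored educational
    achievement scores. Implements the censored bivariate-normal pair
    likelihood for all observation patterns, full-information maximum
    likelihood ACE variance decomposition with socioeconomic-status (SES)
    stratified means and variance components, likelihood-ratio comparison of
    nested models, profile-likelihood confidence intervals, polygenic-score
    analyses (PGS distribution by SES, between-family PGS regression inside
    the twin model, and the within-pair DZ higher-versus-lower-PGS
    contrast), a reproducible analysis pipeline, and a calibrated synthetic
    twin-cohort generator with known truth for estimator validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
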