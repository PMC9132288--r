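Package: aoacorpus
Title: Corpus-Based Age-of-Acquisition Estimation and Validation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimates the age of acquisition (AoA) of words from
    longitudinal child-language corpora in CHAT format, and validates the
    estimates against adult AoA ratings, test-based norms, parent-report
    (CDI) data, and adult lexical decision times. Provides first-occurrence
    extraction under configurable k-child thresholds, reliability analysis
    via two-way random-effects intraclass correlation ICC(2,k) and
    split-half resampling, logistic 50%-acquisition-age (AoA50) fits to
    parent-report curves, frequency adjustment by residualization,
    standardized multiple regression with variance-inflation diagnostics
    and repeated k-fold cross-validation, and a synthetic longitudinal
    corpus generator with known latent acquisition ages for end-to-end
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    stats,
    utils,
    jsonlite,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    car,
    lme4
Config/testthat/edition: 3
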