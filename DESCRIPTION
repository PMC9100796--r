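Package: timeuse24
Title: Reliability and Validity Analysis for 24-Hour Movement Behaviour Measures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for evaluating measurement properties of 24-hour movement
    behaviour instruments. Scores time-use questionnaires into closed daily
    compositions of sleep, sedentary behaviour, light and moderate-to-vigorous
    physical activity; processes thigh-worn inclinometer event streams with
    sleep-diary fusion, non-wear accounting and valid-day averaging; computes
    test-retest reliability and convergent-validity statistics (two-way mixed
    intraclass correlations with confidence intervals, bootstrap Spearman
    correlations, Bland-Altman limits of agreement with proportional bias, and
    Bonett sample-size planning); and simulates cohorts with known latent
    compositions so every pipeline stage can be checked against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
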