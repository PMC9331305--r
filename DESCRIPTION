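Package: catbank
Title: Item-Bank Calibration and Computerized Adaptive Testing for
    Patient-Reported Experience Measures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Engineering toolkit for polytomous item banks measuring
    patient-reported experience: descriptive item screening with
    Cronbach's alpha, item-response-theory assumption checks (polychoric
    correlations, parallel analysis, unweighted-least-squares one-factor
    and bifactor fits, local independence, monotonicity), generalized
    partial credit model (GPCM) calibration by marginal maximum
    likelihood EM, differential item functioning screening via nested
    proportional-odds models with pseudo-R2 magnitude classification,
    expected-a-posteriori scoring with a 0-100 transform, a computerized
    adaptive testing (CAT) simulator with SEM-based stopping, and a
    synthetic-cohort generator with known ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    jsonlite,
    pracma,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
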