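Package: affectdyn
Title: Emotion-Dynamics Indices and Symptom Models for Ecological
    Momentary Assessment Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing intensive longitudinal affect ratings
    collected by ecological momentary assessment (EMA). Implements
    compliance-based data selection, per-person emotion-dynamics indices
    (affect intensity, RMSSD instability, lag-1 autocorrelation inertia
    with day breaks, and Fisher-z emotion differentiation), questionnaire
    subscale scoring with cutoff classification, and staged
    covariate-adjusted logistic and linear regression with nested model
    comparison. A synthetic cohort generator with known person-level
    dynamics and a known symptom-outcome model supports end-to-end
    testing and parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
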