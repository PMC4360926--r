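Package: vitalindex
Title: Admission Vital-Signs Prognostic Index for Sepsis Mortality
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Derivation, scoring, and validation of a simple prognostic index
    for in-hospital mortality among patients hospitalized with sepsis, built
    from admission vital signs (respiratory rate, pulse, mean arterial
    pressure, axillary temperature, and Glasgow coma score). Provides the
    reduced-segmentation index (one point per abnormal vital, maximum 5) and
    the Modified Early Warning Score (MEWS) comparator; a derivation pipeline
    that fits restricted cubic spline logistic risk curves, segments each
    vital into reference and prognostic categories relative to sample-average
    mortality, and extracts clinically usable cutoffs; contingency statistics
    (Woolf odds ratios with Wald confidence intervals); reconstruction of
    per-patient score/outcome records from published per-score mortality
    tables; and a seedable synthetic cohort generator with planted risk
    structure for testing cutoff recovery.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
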