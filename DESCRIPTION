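Package: icubench
Title: Daily ICU Severity Scores and Prognostic Model Validation for
    Cardiac Surgery Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes four daily severity-of-illness scores for postoperative
    cardiac surgery intensive-care patients (CASUS, SOFA, APACHE II and
    SAPS II) from raw physiological observations, together with their Mean-
    and Max-score derivatives over the ICU stay, and benchmarks their
    prognostic performance for ICU mortality with per-day logistic
    recalibration (odds ratios per score point), Hosmer-Lemeshow calibration,
    ROC discrimination and overall correct classification. Includes a seeded
    synthetic cohort generator for postoperative cardiac-surgery ICU stays
    (daily multi-organ physiology, device support flags and a coupled
    death/discharge process) so the full benchmark runs end to end without
    access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    pROC,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
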