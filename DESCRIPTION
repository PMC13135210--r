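Package: teleabx
Title: Propensity-Weighted Comparison of Antibiotic Prescribing in
    Telemedicine and In-Person Pediatric Primary Care
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds episodes of care for pediatric acute respiratory tract
    infections (ARTI) from visit-, prescription- and patient-level tables,
    scores antibiotic guideline concordance by diagnosis, fits a
    practice-clustered propensity model for telemedicine use, constructs
    inverse-probability-of-treatment and overlap weights with standardized-bias
    and prognostic-score balance diagnostics, and estimates average treatment
    effects as differences of Hajek-weighted percentages with cluster-robust
    Wald confidence intervals. Ships a synthetic EHR generator with known
    ground-truth effects for validation, plus subgroup and
    diagnosis-conditional sensitivity analyses.
License: MIT
Encoding: UTF-8
Imports:
    lme4,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
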