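Package: fcleakage
Title: Subject Fingerprinting and Data Leakage in Functional Connectivity Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates multi-scan resting-state fMRI cohorts with a controllable
    subject-fingerprint component, derives static and windowed (dynamic)
    functional connectivity from ROI timeseries, measures subject
    identifiability by cosine-similarity nearest-neighbour matching, and
    quantifies how placing dependent scans or windows of the same subject on
    both sides of a train/test split inflates phenotype prediction accuracy
    relative to subject-disjoint evaluation. Includes Monte-Carlo re-splitting
    experiments with null, legitimate and double-dipping arms, a cross-cohort
    mitigation check, and a reproducible end-to-end pipeline driven by a YAML
    configuration.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    signal,
    stats,
    tools,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
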