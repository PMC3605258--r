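Package: cutlock
Title: Discovery, Lockdown and Validation of Prognostic Expression Cutoffs in AML
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Implements a standardized pipeline for deriving and validating
    prognostic gene-expression cutoffs (BAALC, ERG, MN1, EVI1) for overall
    survival in intermediate cytogenetic risk acute myeloid leukemia:
    probe-set standardization (chip scaling, geometric mean centering,
    mean-variance normalization, per-gene scores), cross-validated
    significance profiling over percentile cutoffs, maximally selected
    logrank cutoffs for skewed markers, cutoff lockdown, and independent
    validation (one-sided logrank, hazard ratios, mutation enrichment,
    multivariate Cox models). Includes a synthetic AML cohort generator
    with planted survival effects so every stage is testable without
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    survival,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
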