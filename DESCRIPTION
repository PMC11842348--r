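Package: qolemwpc
Title: Psychometric Validation and Meaningful-Change Thresholds for the QOL-E Instrument
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scoring, psychometric validation, and meaningful within-patient
    change (MWPC) threshold estimation for the QOL-E, a 29-item
    health-related quality-of-life questionnaire for patients with
    myelodysplastic neoplasms. Provides configurable domain and summary
    scoring standardized to the 0-100 scale, distributional (floor/ceiling)
    summaries, convergent/divergent and known-groups validity against the
    EORTC QLQ-C30 and clinical outcomes, test-retest reliability via
    ICC(A,1) from a two-way mixed ANOVA, internal consistency (Cronbach
    alpha, McDonald omega from a single-factor minimum-residual fit),
    change-score responsiveness, anchor-based responder groups with
    small-group collapsing, empirical-CDF separation checks, and
    triangulation of anchor- and distribution-based estimates (SEM, 0.5*SD,
    minimum possible change) into integer improvement/worsening thresholds.
    A seeded synthetic-cohort generator with a graded ordinal item model
    emulates the pooled multi-trial design so the full pipeline is testable
    without patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    rlang,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr
Config/testthat/edition: 3
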