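Package: drscompare
Title: Head-to-Head Benchmarking of Dementia Risk Scores Against Cognitive Decline
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for comparing composite dementia risk indices (ANU-ADRI,
    CAIDE, CogDrisk, LIBRA, LIBRA2, UKBDRS, UKBDRS-APOE and a Lancet
    Commission risk-ratio based index) as predictors of later cognitive
    function and decline on the Montreal Cognitive Assessment (MoCA).
    Provides a declarative scoring engine driven by editable YAML weight
    tables, including prorating of incomplete scores and demographic
    augmentation or stripping; inverse-probability-of-attrition weighting
    with upper-percentile truncation; linear mixed-effects models of MoCA
    level and annual change with score-by-time interactions and age/sex
    moderation; Mann-Whitney AUC with DeLong variance and paired AUC
    comparison; sensitivity grids over decline thresholds and floor
    exclusions; and a seeded synthetic-cohort generator emulating a
    two-visit ageing cohort with informative attrition, so the whole
    pipeline is testable without access-restricted registry data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    lme4,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
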