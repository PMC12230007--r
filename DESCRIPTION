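Package: icap
Title: Intrinsic Capacity Scoring and Pre/Post Intervention Analysis for
    Older-Adult Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes the WHO-style composite intrinsic capacity (IC) score
    from geriatric functional assessments across five domains (vitality,
    sensory, locomotion, psychological, cognition), classifies participants
    into low/moderate/high capacity bands, and analyses pre/post intervention
    change with generalized estimating equations (exchangeable working
    correlation, robust sandwich variance) chosen per variable type, plus
    standardized effect sizes with bootstrap confidence intervals and Cohen
    banding. Includes a synthetic longitudinal cohort generator with
    configurable true effects, within-subject correlation and dropout, a
    validated CSV cohort interchange format, and a command-line pipeline
    (simulate, score, analyze).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    MASS,
    sandwich,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
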