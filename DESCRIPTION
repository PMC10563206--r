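Package: haisentry
Title: Knowledge-Based Surveillance of Healthcare-Associated Infections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A rule-based surveillance pipeline for healthcare-associated
    infections (HAIs) in inpatient cohorts. Episodes are represented as typed
    eight-group case tuples (demographics, hospitalization status,
    progress-note flags, imaging-report flags, vital signs, clinical
    laboratory, operations, medical orders) built from multi-source electronic
    health records; conjunctive knowledge rules expressed as decision tables
    are matched by a forward inference engine; fired rules are post-processed
    into auditable warnings (best rule per diagnosis, hospital-onset
    classification, repeat-infection suppression, per-diagnosis probability
    thresholds); rule confidences are updated monthly from physician
    confirmation feedback; and surveillance output is scored against gold
    labels with accuracy, sensitivity and specificity stratified by month,
    diagnosis and infection site. A deterministic synthetic inpatient cohort
    generator with rule-consistent infection injection makes every stage
    testable without hospital data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
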