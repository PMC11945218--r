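Package: phenocuff
Title: Rule-Based EHR Phenotyping of Degenerative Rotator Cuff Tear
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Classifies patients as cases or controls for degenerative
    rotator cuff tear from longitudinal coded electronic health record
    (EHR) data. Implements a portable rule engine over CPT, ICD-9-CM and
    ICD-10-CM code groups with temporal windows, visit/mention frequency
    thresholds and post-anchor exclusion logic; ships a code dictionary
    with per-site provenance; computes diagnostic-accuracy metrics against
    a gold standard with an adjudication workflow for gold-label errors;
    and generates seedable synthetic coded-event cohorts (including
    cross-site code-dialect substitutions and gold-label corruption) for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
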