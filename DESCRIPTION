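Package: icuqi
Title: Computable Quality Indicators for Intensive Care Medicine
Version: 0.1.0
Authors@R: person("ICU QI", "Maintainers", email = "icuqi@example.org", role = c("aut", "cre"))
Description: A computer-interpretable representation of the German (DIVI)
    intensive-care quality indicators. Provides a formal indicator model
    (Boolean eligibility criteria over coded medical concepts, timed
    intervention actions, continuous goals and per-1000-patient-day rates),
    a terminology registry with SNOMED CT, LOINC and supplementary DIVI-QI-S
    mappings, an encoder/decoder to CPG-on-EBMonFHIR-shaped FHIR JSON
    resources (PlanDefinition, EvidenceVariable, ActivityDefinition), a
    back-translator to the human-readable intermediate representation used
    for clinician review, a fulfillment-evaluation engine for patient event
    streams, and a seeded synthetic ICU cohort generator for end-to-end
    verification.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
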