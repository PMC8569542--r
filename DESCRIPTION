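Package: ehrscreen
Title: Patient Screening on openEHR-Modelled Health Records
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for cohort selection from electronic health records
    modelled with openEHR-style templates. Screening concepts are derived
    from clinical templates, eligibility criteria are written in a subset
    of the openEHR Expression Language with temporal (Allen interval) and
    collection constraints, templates are mapped to hierarchical
    document-index schemas, and screening conditions are compiled to
    Elasticsearch Query DSL alongside a reference in-memory engine that
    defines the execution semantics. A seeded synthetic-record generator
    provides ground-truth cohorts for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
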