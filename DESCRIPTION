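Package: diag360
Title: Traffic-Light 360-Degree Diagnostic Engine for Type 2 Diabetes Care
Version: 0.1.0
Authors@R: person("diag360", "maintainers", email = "diag360@example.org",
    role = c("aut", "cre"))
Description: A config-driven scoring, classification, visualization and
    advice engine for holistic ("360 degree") diagnosis of people with
    type 2 diabetes in primary care. Ingests clinical measurements and
    questionnaire responses across four domains (body, thinking and
    feeling, behavior, environment), classifies 21 parameters into
    traffic-light statuses via declarative cutoff bands and decision
    rules, renders the profile wheel as SVG with per-parameter detail
    panels, matches flagged parameters to an intervention catalog,
    represents the 15-card motivational-interviewing consultation deck,
    compares baseline and follow-up assessments, and generates seeded
    synthetic patients for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    xml2,
    optparse
Config/testthat/edition: 3
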