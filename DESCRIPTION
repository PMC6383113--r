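Package: alertlog
Title: Tracking Clinician Responses to Noninterruptive Alerts in EHR Access and Audit Logs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for mining electronic health record (EHR) access and audit
    logs to measure how primary care physicians respond to noninterruptive
    clinical decision support alerts delivered to their EHR inbox. Provides a
    validated event-log schema with JSONL/CSV readers and writers, detection
    of first alert openings with delivery-context categories, classification
    of immediate (5-minute) and subsequent (two-day) physician actions,
    point-in-time reconstruction of inbox state by replaying message
    lifecycle events, a seeded synthetic event-stream generator with a
    quota-constructed canonical fixture, and clustered logistic inference via
    generalized estimating equations with exchangeable working correlation
    and robust sandwich standard errors.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    lubridate,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
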