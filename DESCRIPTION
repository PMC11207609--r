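Package: icufusion
Title: ICU Device Data Fusion, Stream Reliability, and Ventilation Analytics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale model of a critical-care data-fusion stack.
    Translates multi-dialect medical-device messages (HL7 v2-like, JSON,
    and proprietary delimited records) into FHIR-style observation records
    with LOINC/UCUM coding; routes observations through an in-memory
    topic/partition broker with node failover and a discrete-event delay
    simulator; computes lung-protective ventilation indices (ventilatory
    ratio, P/F ratio, tidal volume per predicted body weight) and safety
    alerts for ARDS management; provides closed-form and Monte-Carlo
    reliability analysis of repairable broker clusters; and offers a
    stage-graph feature-extraction plus majority-voting ensemble scaffold
    for ARDS classification, together with synthetic generators for
    cohorts, device-message streams, and labeled ventilation datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    nnet,
    pROC,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    e1071,
    xgboost
Suggests:
    knitr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
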