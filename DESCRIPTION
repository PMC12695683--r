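Package: rtimagerisk
Title: Radiobiological Risk Modelling of Daily MV-CBCT Imaging Dose
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Accumulates daily megavoltage cone-beam CT (MV-CBCT) imaging dose
    with treatment dose from DICOM-RT inputs, computes per-organ differential
    dose-volume histograms and mean doses, and evaluates radiobiological risk:
    logistic and Lyman-Kutcher-Burman normal tissue complication probability
    (NTCP), Schneider organ equivalent dose (OED), and BEIR VII-style excess
    absolute risk (EAR) of radiation-induced secondary cancer with age
    modification. Includes cohort-level comparison of imaging protocols with
    paired statistics and age stratification, plus a seeded synthetic DICOM-RT
    phantom-cohort generator so the whole pipeline is testable without patient
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
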