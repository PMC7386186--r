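Package: tbiplanr
Title: Automated Treatment Planning and Safety Checks for Total Body Irradiation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A beam-data-driven toolkit for extended-SSD total body
    irradiation (TBI) planning. Provides a monitor-unit and dose-rate
    hand-calculation engine built on tabulated machine factors (TMR, Sc,
    Sp, spoiler, inverse-square), an automated plan builder with
    deterministic naming, reference points and per-field MU setting via
    normalization and field weights, worksheet generation with a battery
    of pre-treatment safety checks, and incident-learning-system
    analytics (quarterly rates, category breakdowns, overrepresentation
    factors). Plans export to JSON and a minimal DICOM-RT Plan object.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    digest,
    dplyr,
    generics,
    ggplot2,
    glue,
    grDevices,
    graphics,
    jsonlite,
    lubridate,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
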