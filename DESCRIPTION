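Package: saltscore
Title: Scoring National Salt-Iodization Standards Against WHO 2014 Fortification Guidelines
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Compares the iodine amounts and compounds required by national
    salt-iodization standards with the WHO 2014 guidelines on salt
    fortification. Implements the guideline lookup table and its generating
    formula (RNI plus production-to-household losses), midpoint extraction and
    unit-basis conversion for national standards, percent-of-guidelines-met
    scoring and aggregation, a three-way classification of allowed iodine
    compounds, eligibility filtering that links household iodized-salt
    coverage surveys and standard issue dates to median urinary iodine
    concentration (mUIC) assessments, and Pearson correlation of scores with
    mUIC. A synthetic country-data generator with a physiological forward
    model produces realistic standards, intake, coverage and mUIC tables with
    known ground truth, so the full pipeline is testable without external
    data downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
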