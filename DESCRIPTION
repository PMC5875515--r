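Package: plaqueqa
Title: Air Kerma Strength Verification for Preassembled I-125 Eye Plaques
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quality-assurance calculations for episcleral plaque brachytherapy
    with I-125 seeds. Converts dose-calibrator readings of assembled COMS and
    Eye Physics EP917 eye plaques to air kerma strength, decay-corrects
    NIST-traceable assay certificates to the measurement date, computes plaque
    calibration factors and their deviation from per-plaque-type means, and
    flags plaques exceeding a 5 percent action limit. Includes per-seed
    contribution analysis for plaque uniformity, per-type summary statistics,
    a synthetic-record simulator with measurement-error injection for
    estimating the action limit's sensitivity, and worksheet readers/writers.
License: MIT
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests: testthat (>= 3.0.0), optparse, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
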