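Package: luxscreen
Title: Dual-Luciferase Reporter Screen Analysis and Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for dual-luciferase (Firefly/Renilla) reporter
    screens of yeast ribosomal-variant-strain libraries and small-molecule
    dose panels: plate-readout import and validation, Grubbs outlier
    filtering, wild-type normalization, inert-circle and quadrant
    classification of strains with selective-hit calling, dose-response
    normalization, trend testing and compound triage, plus a calibrated
    synthetic plate-readout generator so the whole pipeline can be exercised
    and verified without instrument data.
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
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
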