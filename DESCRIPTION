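Package: flashqa
Title: Log-File Dose Reconstruction and QA for UHDR Proton Pencil-Beam Scanning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quality-assurance toolkit for FLASH (ultra-high dose rate) proton
    pencil-beam-scanning deliveries. Reconstructs the delivered 2D dose and
    PBS-average (Folkerts) dose-rate maps from 1 kHz machine delivery logs
    (dose-monitor and scanning-magnet Hall-sensor traces), implements a
    simplified TPS-side dose and dose-rate model, runs patient-specific and
    daily QA checks (five-spot position/size fit, central dose scaling,
    mean-deviation boosting, 3%/3 mm gamma analysis in the 90% isodose,
    UHDR dose-rate floor), and assembles blinding-aware delivery reports.
    Includes a deterministic delivery simulator (spot dead times, pauses,
    sensor noise) so the whole pipeline is testable without machine data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
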