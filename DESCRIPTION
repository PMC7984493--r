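Package: repaintr
Title: Interplay-Effect Simulation for Volumetric Repainting in Proton
    Pencil-Beam Scanning
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Simulates the interplay effect between pencil-beam-scanning
    (PBS) proton delivery and breathing motion for lung targets, and
    selects the number of volumetric repaintings needed for an acceptable
    plan.  Provides a seeded synthetic 4D phantom generator, a simplified
    single-field-uniform-dose (SFUD) spot-plan generator with an analytic
    Bragg-peak dose engine, an alternating-order ("down"/"up") volumetric
    repainting sequencer honouring the machine minimum monitor unit, a
    delivery time-structure model, time-resolved dose accumulation over
    ten breathing starting phases, DVH worst-case-scenario and bandwidth
    metrics, and a two-tier criteria engine that escalates the number of
    repaintings until the plan is acceptable.
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
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
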