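Package: barriereis
Title: Equivalent-Circuit Impedance Analysis of Epithelial Barrier Integrity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Analysis toolkit for electrical readouts of intestinal epithelial
    barrier integrity across three measurement platforms: equivalent-circuit
    modelling and complex non-linear least-squares (CNLS) fitting of
    electrochemical impedance spectra from 3D bioelectronic transmembrane
    devices (extracting the barrier resistance Rb), transepithelial electrical
    resistance (TEER) from voltohmmeter readings on 2D insert cultures, and
    Ussing-chamber resistance from clamped current traces on ex vivo tissue.
    Includes baseline-normalised calcium-switch (EGTA) disruption/recovery
    statistics with Holm-Sidak multiple-comparison correction, quality-control
    filtering of device trajectories, and seeded synthetic-data generators for
    every modality so the full pipeline is testable without instrument data.
License: MIT
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
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
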