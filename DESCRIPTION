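Package: somnotherm
Title: Sleep-Temperature Coupling Analysis for Rodent Polysomnography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Rule-based vigilance-state scoring of ECoG/LFP + EMG
    recordings in 5-second epochs, Welch power spectral density and
    delta-band ratio statistics, wake-to-NREM transition-locked analysis
    with classification of the coincident core-temperature change, exact
    r x c contingency tests with Holm-Sidak adjustment, and
    warmth-induced somnogenesis quantification. Ships a synthetic
    polysomnography generator with genotype presets (wild-type, Dravet
    model, rescued) so the full pipeline is testable end-to-end without
    animal recordings, plus EDF and CSV readers and writers for the
    on-disk formats the pipeline touches.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    car
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
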