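Package: nkscreen
Title: Luciferase-Based Nucleoside Kinase Substrate Screening in Plate Format
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for high-throughput nucleoside kinase (NK)
    substrate screening with a luciferase ATP-depletion readout in 96-well
    plates. Reads plate layouts, plate-reader luminescence exports and HPLC
    peak tables; fits per-donor standard curves and ranks alternative
    phosphate-donor acceptance; quantifies consumed phosphate donor and
    nucleoside monophosphate product formation with same-plate background
    controls; computes the Z-prime plate-quality statistic and
    autoluminescence/inhibition interference checks; quantifies conversion
    from HPLC peak areas by retention-time matching and compares the two
    methods. A synthetic-data module generates plates and matched peak
    tables with known ground truth so the whole pipeline is testable
    without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
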