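Package: nanoevent
Title: Translocation Event Extraction and Analysis for Solid-State
    Nanopore Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantitative analysis of ionic-current recordings
    from solid-state nanopore experiments. Detects translocation events by
    threshold crossing with a baseline-tolerance closure rule, computes
    dwell times and percentage current blockage, fits blockage-depth
    populations with seeded Gaussian mixtures and dwell-time distributions
    by exponential maximum likelihood, classifies events by duration and
    blockade asymmetry, sizes pores from current-voltage sweeps using the
    cylindrical-pore conductance model, and provides deterministic
    calculators for rolling circle amplification product length, tandem
    repeat counts, and dilution concentrations. A synthetic trace
    simulator with a ground-truth event ledger supports validation of
    every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    signal,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    optparse
Config/testthat/edition: 3
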