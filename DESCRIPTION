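Package: mdplaque
Title: Calcium Transient Quantification and Functional Connectomics of
    Macula Densa Plaques
Version: 0.1.0
Authors@R:
    person("mdplaque", "developers", email = "mdplaque@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for intravital calcium-imaging recordings of
    the renal macula densa (MD). Extracts per-cell fluorescence traces from
    image stacks or trace tables, normalizes to baseline (F/F0), detects
    Ca2+ transients and summarizes per-cell firing frequency, spike width
    (FWHM), peak amplitude and cumulative activity, builds the thresholded
    Pearson-correlation "MD connectome" with hub and lone cell
    classification, and quantifies whole-plaque oscillation regularity and
    coupling to arteriole vasomotion. Includes a coupled-oscillator plaque
    simulator with wild-type and NGFR-knockout presets and planted ground
    truth for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    yaml,
    igraph,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
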