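Package: hpdsim
Title: Neural Mass Simulation and Quantification of Hippocampal Paroxysmal
    Discharges Under Direct-Current Stimulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates local field potentials of the epileptic dentate gyrus
    with a three-subpopulation neural mass model whose input noise is switched
    by a gamma-renewal modulation function, producing realistic hippocampal
    paroxysmal discharges (HPD). Adds a biophysical model of local
    direct-current stimulation: an electrode-electrolyte interface circuit,
    per-population coupling coefficients converting tissue current into
    membrane polarization, and a bipolar point-source electric-field
    calculator. Includes the matching detection pipeline (20-80 Hz band-pass,
    Page-Hinkley spike detection, slot merging) and feature set (duration,
    energy, peak count, RMS), plus in-silico stimulation experiments:
    coupling-coefficient cartography, epoch-based protocols and rank-sum
    condition comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    fitdistrplus,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
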