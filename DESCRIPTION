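Package: ca1sep
Title: Pattern Separation in a Feedforward CA3/EC to CA1 Network Model
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying input-to-output pattern separation in a
    feedforward model of hippocampal area CA1 driven by CA3 (Schaffer
    collateral) and entorhinal cortex (perforant path) inputs within a single
    gamma cycle. Provides exact-count binary population patterns with
    controlled Hamming distances, random bipartite feedforward connectivity
    with at most one contact per cell pair, a calibrated threshold-neuron
    surrogate behind a pluggable response-model contract, Boltzmann (sigmoid)
    input-output calibration, analytic binomial and exact hypergeometric
    Hamming-distance theory, and an end-to-end four-condition separation
    experiment (similar/distinct pairs for each pathway) with plain-text,
    seed-reproducible artifacts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
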