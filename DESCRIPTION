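Package: fnirsplv
Title: Phase-Locking Connectivity Analysis for Prefrontal fNIRS Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of block-design prefrontal functional
    near-infrared spectroscopy (fNIRS) experiments contrasting two task
    conditions. Provides a synthetic data generator (hemodynamic responses,
    physiological noise, planted phase coupling, behavioral selection logs),
    the modified Beer-Lambert forward and inverse models, a preprocessing
    chain (anti-aliased resampling, zero-phase Butterworth band-pass,
    epoching with baseline correction), Hilbert-phase phase-locking-value
    (PLV) connectivity at channel and region-of-interest level with
    seed-based profiles, weighted graph metrics (global/local efficiency,
    nodal strength, Onnela clustering), and group-level paired inference
    with Benjamini-Hochberg false-discovery-rate control and a-priori
    power analysis for paired designs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    igraph,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
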