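Package: prcsync
Title: Phase-Resetting-Curve Prediction of Synchrony in Pulse-Coupled
    Neuronal Oscillators with Conduction Delays
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing synchronization of two reciprocally
    pulse-coupled neuronal oscillators with axonal conduction delays using
    phase resetting curves (PRCs). Fits polynomial PRC models with
    phase-dependent noise envelopes from noisy (stimulus phase, resetting)
    measurements, classifies them as Type I or Type II, finds all 1:1
    phase-locked modes of a delayed two-cell circuit together with their
    stability, evaluates a linearized expression for the near-synchronous
    time lag under period and delay heterogeneity, and simulates a noisy
    event-driven iterated map whose lag histograms and circular statistics
    reproduce the phenomenology of hybrid (dynamic-clamp) circuits.
    Includes generators for canonical excitatory and inhibitory Type I and
    Type II PRC templates so every stage is testable without
    electrophysiology.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    stats,
    tibble,
    utils
Suggests:
    ggplot2,
    optparse,
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
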