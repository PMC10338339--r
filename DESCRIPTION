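Package: pcqls
Title: Photon-Counting Quantum Light Spectroscopy of a Heralded Single-Photon Experiment
Version: 0.1.0
Authors@R:
    person("PCQLS", "Developers", email = "pcqls@example.org", role = c("aut", "cre"))
Description: Monte Carlo simulation and analysis of photon-counting quantum
    light spectroscopy (PCQLS) experiments in which a heralded single-photon
    source excites a fluorescent sample (such as the LH2 antenna complex of
    purple bacteria) and time-tagged detector streams are analysed by
    coincidence counting. Provides a columnar time-tag data model with
    plain-text I/O, closed-form counting-statistics models (thermal pair-number
    statistics of a pulsed down-conversion source, multi-photon weights of
    heralded pulses, the heralded second-order coherence estimate, and the
    geometric distribution of heralds per heralded fluorescence detection), a
    stochastic-trajectory simulator emitting realistic multi-channel time-tag
    streams, coincidence analyses (herald-fluorescence cross-correlation,
    gated three-detector conditional g2(0) with Poisson errors, and the
    heralds-per-fluorescence distribution), fluorescence lifetime extraction by
    Poisson maximum likelihood with instrument-response reconvolution, and an
    end-to-end pipeline with a command-line interface that reproduces the
    standard result set of such an experiment from configuration alone.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
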