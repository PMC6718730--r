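Package: nlariRelay
Title: Relay-Chain Spike Propagation with a Nonlinear Autoregressive
    Membrane-Potential Encoder
Version: 0.3.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis of temporal spike-train propagation
    through chains of relay interneurons. Each relay encodes its drive with a
    second-order nonlinear autoregressive (NLARI) membrane-potential process
    with a bounded odd restoring force; a multithreshold amplitude decoder
    corrects over- and under-responses between relays. The package provides
    the stochastic difference equation and its deterministic regime analysis
    (fixed point, period-2 cycle, chaos, classified by the stability
    coefficient), all-or-none and encoder-decoder relay propagation, fidelity
    metrics (propagation success rate, network-level precision, synchronous
    spike-event mistake probabilities, waiting-time bounds), ordinary
    least-squares estimation of the encoder coefficients with waveform
    indicators and a stable fixed-point test, synthetic stimulus generators,
    and reproducible Monte-Carlo reliability sweeps over the stability
    coefficient grid.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
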