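Package: cqdecode
Title: Competitive Queuing Analysis of Preparatory Sequence Codes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Simulation and decoding pipeline for studying competitive queuing
    (CQ) of serial order in multichannel neurophysiological recordings of cued
    finger-press sequences. Generates ground-truth-known synthetic MEG-like and
    EMG-like epochs with graded preparatory superposition of press-specific
    spatial patterns, decodes per-press posterior probabilities with a
    Gaussian-linear (LDA) classifier over short time windows, quantifies the CQ
    distance statistic across within-sequence and transfer (temporal, spatial,
    positional) regimes, runs temporal-proximity and muscular confound
    controls, maps CQ and decoding accuracy across sensors with a searchlight,
    and simulates the temporal-context competitive-queuing network that
    motivates the analysis.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    data.table
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
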