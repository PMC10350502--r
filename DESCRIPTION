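Package: microspike
Title: Excitable Microlaser Neurons and Spike-Based Digit Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation of excitable micropillar-laser neurons described by a
    three-variable Yamada model with saturable absorber, driven through an
    incoherent pump that encodes binary pixel sequences. Provides quiet-state
    computation, stiff slow-fast integration, spike detection and latency
    measurement, excitability maps (minimum run length to spike, pattern
    discrimination regions, spike-latency-difference surfaces, self-pulsing
    onset), row/column receptive fields over 5x5 binary digit images, and
    three online spike-code classifiers (event-based, spike-time stamps,
    rank order) together with codebook construction, minimal-feature-subset
    search and random-delay search.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
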