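Package: cycnoise
Title: Protein Noise Decomposition Under Noisy Cell-Cycle and Gene-Duplication Timing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies how bursty gene expression, random cell-division and
    genome-duplication timing, and molecule-partitioning errors combine to set
    the mean and cell-to-cell variability (squared coefficient of variation)
    of protein copy numbers in single-cell lineages. Provides exact closed-form
    steady-state formulas, an exact moment-ODE engine for phase-type (mixture of
    Erlang) cell-cycle clocks, an event-driven stochastic simulator that
    cross-validates the analytics, and parameter-inference procedures for burst
    size and partitioning error from Fano-factor measurements.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
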