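Package: nlutadex
Title: Nyquist Lookup-Table Approximation and Multiplierless Fixed-Point
    Emulation of the Adaptive Exponential Integrate-and-Fire Neuron
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the adaptive exponential integrate-and-fire (ADEX)
    neuron and a lookup-table variant in which the exponential spike-initiation
    term is replaced by a Nyquist-rate sampled table (N-LUT-ADEX). Provides the
    table design procedure (spectral bandwidth estimate of the voltage
    nonlinearity, point-count selection by the sampling theorem), a bit-exact
    emulation of a multiplierless fixed-point hardware pipeline (canonical
    signed-digit constant decomposition, shift-and-add scaling, operation
    census), quantitative model-comparison metrics (mean absolute error,
    correlation, trough error, mean relative spike-time error), phase-plane
    diagnostics (nullclines, Jacobians), and a randomly connected
    excitatory/inhibitory population simulation with raster and population
    rhythm analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
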