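Package: gndfit
Title: Generalized Normal Distribution Characterization of Fast Nanopore
    Translocation Events
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Parameterization of short-lived ionic current blockades in
    single-channel nanopore recordings with a five-parameter generalized
    normal model (open-pore current, blockade amplitude, localization,
    scale and shape). Provides the closed-form distribution functions,
    dwell-time reconstruction by equal-area back-mapping, validation of
    whether a blockade reached its true amplitude, the per-event minimal
    required sampling frequency, robust threshold event localization,
    bounded nonlinear least-squares fitting, digital Gaussian and
    continuous-time 4-pole Bessel filter simulation, a synthetic trace
    generator with known ground truth, a low-pass filter recommendation
    sweep, a SQLite event store and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    stats,
    tools,
    utils,
    yaml
Suggests:
    deSolve,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
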