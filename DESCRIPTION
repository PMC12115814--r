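Package: surfnet
Title: Topological Surface-Network Model of Brain Excitations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulator and analysis toolkit for a topological surface-network
    model of brain electrical activity. Provides truncated Riemann theta
    functions with half-integer characteristics and the spin topology number
    they carry, hyperelliptic one-forms and their pinch-expansion
    coefficients, Schwarz triangle tilings of the sphere with the predicted
    EEG frequency-band and amplitude table, fractional-degree Legendre
    tiling modes with their eigenvalues and norms, sech-profile soliton
    spike-train synthesis and nonlinear least-squares pinch-parameter
    fitting, the helical magnetic field and proton-spin memory ledger
    (alignment, thermal and MRI stability, engram size and creation time),
    a modal Green's-function EEG response operator, and K-complex and
    sleep-spindle waveform synthesis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
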