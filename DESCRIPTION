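Package: plvsleep
Title: Sleep-Stage Functional Connectivity with Phase-Locking Values and
    Frequency-Band Fusion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for EEG-based sleep staging through functional
    brain connectivity. Computes phase-locking value (PLV) connectivity
    matrices per 30 s epoch across six canonical frequency bands (delta to
    gamma), curates hypnograms, ranks channel-pair features with the
    point-biserial r-squared, thresholds stage-average networks at the
    no-isolated-node point, and classifies REM/N2/N3 epochs with a
    Gaussian-kernel support vector machine under feature-level, stacking and
    hybrid band-fusion strategies. Includes a calibrated synthetic
    coupled-oscillator EEG generator with analytically known PLV targets, and
    a minimal EDF reader/writer for round-trip testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
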