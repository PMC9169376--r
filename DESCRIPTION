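Package: lithowarn
Title: Early-Warning Classification of Laser Lithotripsy Shockwave Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for an early-warning system for retrograde intrarenal
    surgery (RIRS) laser lithotripsy. Accelerometer shockwave traces sampled
    at 100 Hz are sliced into 0.5 s windows, transformed with a single-level
    discrete wavelet transform (Haar, Daubechies, reverse biorthogonal and
    discrete Meyer families), and classified into Idle / Stone / Tissue
    states with a random forest. Includes a seeded synthetic shockwave
    simulator, FFT-based spectral separability analysis, a repeated
    stratified cross-validation harness with normalized confusion matrices
    and one-vs-rest ROC averaging, a uniform dummy-data null check, and a
    sliding-window streaming monitor with per-decision latency accounting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    randomForest,
    stats,
    utils
Suggests:
    jsonlite,
    knitr,
    optparse,
    pROC,
    readxl,
    rmarkdown,
    testthat (>= 3.0.0),
    yaml
VignetteBuilder: knitr
Config/testthat/edition: 3
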