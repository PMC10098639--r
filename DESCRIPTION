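Package: mexr
Title: Micro-Expression Recognition with a Double-Stream 3D Convolutional Network
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end pipeline for recognizing brief, low-intensity facial
    micro-expressions in short video clips. Provides apex-centered frame
    selection, Eulerian video magnification (Laplacian pyramid with ideal
    temporal bandpass), dense Farneback optical-flow sequence construction,
    a double-stream 3D convolutional network with a gradient-reversal domain
    discriminator for supervised domain adaptation from macro-expression
    corpora, and a leave-one-subject-out evaluation harness reporting
    unweighted F1, unweighted average recall, and mean accuracy. Includes a
    synthetic clip generator so the full pipeline is testable without
    license-gated corpora.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    tibble,
    stats,
    utils,
    jsonlite,
    yaml,
    png
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
NeedsCompilation: yes
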