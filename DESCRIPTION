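Package: holophase
Title: Adaptive-Constraint Iterative Phase Retrieval for Single-Shot
    In-Line Digital Holography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reconstructs complex optical wave fields (amplitude and
    quantitative phase) from a single in-line (Gabor) hologram by
    iterative phase retrieval with adaptive support constraints built
    from binary mathematical morphology.  Provides band-limited
    angular-spectrum free-space propagation with Tamura-coefficient
    autofocus, first-principles binary morphology (erosion, dilation,
    opening, closing and open-closing / close-opening cascades),
    Poisson-model minimum-error thresholding, static-support and
    multi-distance phase-retrieval baselines, a synthetic hologram
    simulator with calibrated additive Gaussian noise, and normalized
    mean-square-error reconstruction metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    graphics,
    grDevices,
    optparse,
    png,
    stats,
    tiff,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
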