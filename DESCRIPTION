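Package: photonFFS
Title: Fluorescence Lifetime Fluctuation Spectroscopy and Image Scanning
    Microscopy on Photon Streams
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis toolkit for single-photon microscopy with asynchronous
    read-out SPAD array detectors. Works directly on spatiotemporally tagged
    photon event lists (detector channel, absolute time, start-stop microtime)
    to perform spot-variation fluorescence correlation spectroscopy with
    diffusion-law and confinement-strength analysis, dual-color
    cross-correlation spectroscopy, TCSPC lifetime fitting and phasor-plot
    segmentation, and adaptive pixel-reassignment image scanning microscopy
    (intensity and lifetime). Includes a Brownian/trap/hop photon-emission
    simulator that stands in for the instrument, a self-describing columnar
    on-disk event-list format, and condensate-level statistics (particle shape
    analysis, k-means with elbow selection, covariance confidence ellipses,
    Welch's t-test).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    Rcpp,
    jsonlite,
    data.table,
    minpack.lm,
    EBImage
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
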