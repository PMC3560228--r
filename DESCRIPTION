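Package: capdens
Title: Automated Functional Capillary Density from Microcirculation Video
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fully automated analysis of sidestream dark field (SDF) and
    orthogonal polarization spectral microcirculation video. Stabilizes
    handheld recordings by control-point block matching, segments capillaries
    with multi-level thresholding and Euclidean-distance-transform pixel
    verification (diameter, angle and contrast-ratio criteria), classifies
    perfused vessels by temporal differencing of segmented frames, and
    computes area- and length-based functional capillary density (FCD).
    Includes a synthetic phantom generator with ground truth for validation
    and paired statistics for baseline-versus-condition FCD tables.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    jsonlite,
    png,
    Rcpp,
    stats,
    tiff,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
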