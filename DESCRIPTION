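Package: lumenline
Title: Centerline and Cross-Section Quantification of Vessel Lumina in 3D
    Tomograms
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies the lumen of non-cylindrical, constricted and
    bifurcated blood-vessel segments from three-dimensional tomography.
    Provides lumen segmentation preprocessing (3D median smoothing, seeded
    region growing, ball-opening cleanup), an iterative relaxation-stabilized
    centerline estimator with full residual history, cross-sectional area
    profiling in planes orthogonal to the centerline, pairwise shrinkage
    profiles between preparation states, and joint-histogram multi-Gaussian
    comparison of two registered imaging modalities. A synthetic tubular
    phantom generator with analytic ground truth makes every stage testable.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    minpack.lm,
    stats,
    utils,
    tools,
    graphics,
    tiff,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
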