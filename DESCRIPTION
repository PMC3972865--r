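Package: mttex
Title: Texture Analysis of Cortical Microtubule Micrographs via
    Bidimensional Empirical Mode Decomposition and Co-occurrence Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies the arrangement of plant cortical microtubules in
    fluorescence micrographs. Images are enhanced by Bidimensional
    Empirical Mode Decomposition (BEMD): iterative sifting against upper
    and lower extrema envelope surfaces splits an image into intrinsic
    mode functions (IMFs) of decreasing spatial frequency plus a smooth
    residue, and the sharpest IMF is selected by a grey-level
    co-occurrence matrix (GLCM) contrast criterion. Five Haralick texture
    features (angular second moment, entropy, inverse difference moment,
    variance, contrast) are extracted in four directions from the
    selected image, and two groups of micrographs are compared feature by
    feature with Welch's t-test. A deterministic synthetic generator of
    microtubule-like fiber images (ordered and disordered orientation
    regimes) supports validation without micrographs, and a command-line
    script exposes the decompose/features/compare/simulate workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
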