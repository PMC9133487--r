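Package: visoximetry
Title: Visible-Light OCT Parafoveal Retinal Oximetry
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A tested re-implementation of a visible-light optical coherence
    tomography (VIS-OCT) oximetry pipeline for parafoveal retinal vessels:
    synthetic spectral-domain OCT phantom generation with known ground truth,
    full-band and short-time-Fourier-transform sub-band reconstruction,
    retinal pigment epithelium and inner limiting membrane segmentation with
    iterative polynomial outlier rejection and coefficient-of-variation
    B-scan rejection, depth-resolved spectral extraction with Beer-Lambert
    least-squares oxygen saturation inversion, vessel topographic
    morphometry, and per-eye and per-segment statistical summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    EBImage,
    pracma,
    igraph,
    jsonlite,
    yaml,
    tiff
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
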