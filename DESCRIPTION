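Package: flimcoreg
Title: Co-Registration of Full-Spectral FLIM Images with H&E Histology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Pipeline for co-registering full-spectral autofluorescence
    lifetime microscopy (FS-FLIM) hypercubes with H&E-stained histology
    images. Covers lifetime image reconstruction by mono-exponential
    least-squares fitting with spectral smoothing and photon-count
    filtering, histology background masking, unpaired FLIM-to-histology
    image translation with a cycle-consistent adversarial objective,
    homography estimation by gradient descent on a windowed partial
    photometric L1 loss, mosaic stitching of registered tiles, and
    registration-quality metrics. Includes a synthetic phantom generator
    so the full pipeline is testable against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    tools,
    jsonlite,
    png,
    tiff
Suggests:
    testthat (>= 3.0.0),
    minpack.lm
Config/testthat/edition: 3
RoxygenNote: 7.3.3
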