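Package: rendereval
Title: Fidelity of 2D Images Rendered from Photogrammetric 3D Specimen Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative evaluation of how photogrammetric imaging parameters
    affect the fidelity of 2D images rendered from 3D specimen models.
    Enumerates turntable acquisition plans (camera stations on concentric
    tilt rings with configurable horizontal step), compares masked
    original/rendered image pairs with per-channel percent RGB similarity,
    the structural similarity index (SSIM) and thresholded difference maps,
    scores geometric accuracy as mean absolute error over morphometric
    measurements with per-feature success accounting, and aggregates
    per-scenario summary tables with best-model selection. A synthetic-data
    generator produces masked beetle-like specimen images at three view
    angles with controlled degradations (blur, channel shift, noise, scale
    error, feature dropout) so the full pipeline is testable without
    photogrammetry software or physical specimens.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    png,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
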