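Package: scanforge
Title: Focus Stacking, Specimen Masking and Camera-Pose Priors for
    Small-Specimen Photogrammetry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computational core of a two-axis turntable photogrammetry
    pipeline for pinned arthropod specimens. Scores per-image sharpness
    with the variance of a 3x3 Laplacian and filters focal stacks,
    registers stack images to the most distal focal plane with a
    scale-plus-translation model, fuses aligned stacks into extended
    depth of field (EDOF) images by winner-takes-all selection of the
    locally sharpest plane, removes the background with a five-step
    masking routine (denoise, CLAHE enhancement, edge detection,
    adaptive-threshold infill removal, connected-component cleaning),
    embeds the camera metadata photogrammetry software needs, and
    computes analytic camera-pose priors for every gimbal orientation,
    serialized as an AliceVision-dialect .sfm scene. Also provides mesh
    metrology (gauge-cube step heights, closed-mesh surface area and
    volume, longest body axis), the Feltz-Miller asymptotic test for
    equality of coefficients of variation, and seeded synthetic-fixture
    generators with ground truth for end-to-end testing without
    scanner hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    Rcpp,
    jsonlite,
    png,
    tiff,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
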