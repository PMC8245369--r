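Package: rodtwist
Title: Three-Dimensional Twist and Bend Quantification for Rod-Shaped Plant Organs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Quantifies twisting and bending of rod-shaped plant organs
    (e.g. the Arabidopsis petiole) from manually tracked 3D curves of the
    organ midline and its two margins. Tracked points are denoised with a
    Gaussian filter over chord length, converted to smooth curves by cubic
    interpolation, and a material frame (lateral, longitudinal, adaxial) is
    constructed on cross-sections perpendicular to the midline at uniform
    arc-length steps. Local twist and bending rates and cumulative angles
    are extracted from arc-length derivatives of the frame vectors. Includes
    a geometric helix model estimating the differential-growth length ratio
    implied by a measured twist, a synthetic rod generator with prescribed
    twist/bend profiles and tracking noise for ground-truth validation, and
    a command-line interface for the measure/simulate workflows.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
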