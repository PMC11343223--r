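Package: pillartrack
Title: Pillar-Deflection Tracking and Contractility Analysis for Engineered
    Cardiac Microbundles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Automated analysis of brightfield time-lapse movies of engineered
    cardiac microbundles suspended between two elastomeric pillars. Segments
    the pillar caps by local Otsu thresholding, tracks their deflection with
    Shi-Tomasi feature detection and pyramidal Lucas-Kanade sparse optical
    flow, segments the displacement signal into beats, and derives
    contractility metrics: twitch force via Hooke's law with cantilever-beam
    stiffness, tissue stress, beating rate, contraction and relaxation
    velocities, and beat durations (FWHM, FW80M). Includes drift detection
    with per-beat re-baselining, irregular-beat warnings, a mask-perturbation
    sensitivity protocol, and a synthetic movie generator with ground truth
    for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
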