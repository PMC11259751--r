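Package: earscaling
Title: Allometric Scaling and Acoustic Function of the Canid Middle Ear
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Morphometric and functional analysis of middle- and inner-ear
    structures measured from micro-CT reconstructions of dog skulls. Provides
    derived morphometric estimators (elliptical tympanic-membrane area, ossicle
    mass from volume and density, cephalic index, anatomical area ratios),
    log-log ordinary least-squares scaling analysis against skull metrics with
    tests against isometric slopes, standardized-residual outlier detection and
    projection of held-out specimens, lumped-compliance acoustic predictions of
    low-frequency impedance and eardrum-velocity gains, a cube-root
    ossicular-mass predictor of high-frequency hearing limits, audiogram limit
    shifting, and a calibrated synthetic-cohort generator for
    parameter-recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
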