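Package: smfmap
Title: Mapping and Source Modelling of Static Magnetic Fields Near Phone Screens
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Processing pipeline for grid maps of the static magnetic field
    (SMF) measured above mobile-phone screens: replicate averaging, background
    subtraction, hot-spot detection, a four-component measurement uncertainty
    budget combined in quadrature, fitting of a single-loop-of-current (SLC)
    source model with exponential and power-law comparison regressions,
    extrapolation of field and gradient to the screen surface, threshold
    distance solving, and full 3D Biot-Savart evaluation of the field on
    triangulated head-surface meshes, including geomagnetic superposition and
    hypomagnetic (near-zero field) zone search. Includes a synthetic-data
    generator emulating the tri-axial magnetometer measurement protocol so the
    whole pipeline is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
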