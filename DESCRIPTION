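Package: spinemat
Title: Supine Spinal Curvature Analysis and Mattress Support Mechanics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing sagittal spinal curvature measured in the
    supine position with a flexible curvature-measurement tape, and for
    predicting how mattress and pillow stiffness shape that curvature.
    Reconstructs a continuous back profile from three-point arc/line tape
    elements, extracts torso-inclination and lordosis-distance alignment
    metrics via a tangent support-line construction, fits monotone
    pressure-deflection laws to compressive foam stress-strain data, and
    solves a reduced-order sagittal equilibrium model of an articulated
    body chain resting on a nonlinear elastic (Winkler-type) foundation,
    yielding contact-pressure profiles, contact areas and intervertebral
    disc load proxies.  Includes a seeded synthetic-cohort generator for
    crossover mattress studies and paired-contrast reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
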