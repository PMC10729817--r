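Package: spinsense
Title: Rotation-Direction Detection for Spinning Translucent Objects in
    Multi-Plane Bright-Field Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Determines the rotation direction (clockwise, counterclockwise,
    or non-rotating) of translucent, axially symmetric spinning objects such
    as the human sperm head from multi-plane bright-field image stacks.
    Implements a weak-phase-object scalar-diffraction image-formation
    simulator with defocus and spherical aberration (reproducing the
    through-focus contrast-inversion effect), a synthetic 4D phantom
    generator with known ground-truth rotation labels, maximum-intensity
    projection of piezo rising-slope z-stacks, a moment-based head tracker,
    the perpendicular intensity-profile (bb') weighted-average trace, and
    per-cell direction classification with population-level reporting.
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
    yaml,
    tiff,
    EBImage
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
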