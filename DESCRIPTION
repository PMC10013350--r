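Package: woundfield
Title: Quantitative Analysis of Electric-Field Guided Wound Healing Assays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing and analysing bioelectronic microfluidic
    scratch-wound assays under galvanostatic direct-current stimulation.
    Provides parametric microchannel-network layouts and their rasterisation,
    a quasi-static finite-difference solver for the in-plane electric field
    and current density, joule-heating and transient heat-diffusion
    dosimetry, electrode charge budgeting, colorimetric pH calibration and
    tracking from polyaniline-coated channels, wound-closure quantification
    (segmentation, normalised closure curves, kymographs, track directedness),
    and a seeded synthetic-data generator producing ground-truthed migration
    tracks, phase-contrast-like image stacks and pH-reporting colour stacks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    Matrix,
    methods,
    utils,
    stats,
    grDevices,
    tiff,
    yaml,
    jsonlite,
    minpack.lm,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
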