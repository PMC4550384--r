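Package: rfivm
Title: Simulation and Quantification of Radiofrequency Hyperthermia
    Intravital Microscopy
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for studying mild radiofrequency (RF) hyperthermia of
    tumors as observed by multichannel intravital microscopy (IVM).
    Implements the dielectric heating-rate relation for lossy tissues, the
    reconstruction of electric fields from voltage-grid measurements, a
    lumped thermal simulator with a set-point power controller, a seeded
    generator of synthetic three-channel IVM time-lapse stacks with
    temperature-dependent tracer extravasation, and a mask-based
    quantification pipeline (global-threshold segmentation, binary mask
    algebra, morphological cleanup, rigid jitter correction) yielding the
    positive area fraction (PAF), relative tumor dye intensity (RTDI) and
    relative increase in albumin fluorescence (RAIF) perfusion statistics.
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
    data.table
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
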