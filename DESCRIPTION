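Package: fapscreen
Title: Ratiometric pH-Sensor Endocytosis Assay Simulation and Screen
    Statistics
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Simulation and analysis toolkit for dual-excitation ratiometric
    pH-sensor endocytosis assays run in 96-well plates. Models the pH
    dependence of the 561/640 excitation ratio of a FAP-bound tandem
    Cy3/malachite-green dye, fits and inverts calibration sigmoids, converts
    well ratios to endosomal receptor fractions through a two-compartment
    mixing model, simulates clathrin-mediated receptor internalization
    kinetics and In/Sur uptake experiments, renders seeded synthetic
    dual-channel plate images with realistic noise structure, quantifies
    background-corrected well ratios from images, and computes RNAi screen
    statistics: Z'-factor plate QC, per-well log2 fold change against the
    plate's negative-control median, paired SSMD, dual-flashlight tables and
    hit calling.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    grDevices,
    jsonlite,
    minpack.lm,
    tiff,
    png
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
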