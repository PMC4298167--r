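Package: rootcell
Title: Quantification of Root Cross-Section Anatomy from Micrographs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Semi-automated quantification of anatomical traits in transverse
    root-section images of cereal seedlings. Segments the whole root, the stele,
    the central metaxylem vessels and the cortex from bright-cell-wall
    (autofluorescence) or bright-field micrographs, derives tissue areas, and
    counts cortical cell layers and cells per cell file by detecting intensity
    maxima along lines in a polar-transformed image, with extrapolation from
    partial coverage. Includes a synthetic root-phantom generator with exact
    ground truth for validation, a batch pipeline, tabulated output, overlay
    rendering and ROI export.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    tiff,
    png,
    optparse
Config/testthat/edition: 3
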