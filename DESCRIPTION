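Package: fociquant
Title: Batch Quantification of DNA Damage Foci in Fluorescence Microscopy Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Counts and measures DNA double-strand-break foci (gamma-H2AX-style
    puncta) per nucleus in paired batches of single-channel fluorescence images.
    Nuclei are segmented from a marker channel (DAPI, NeuN or a transduction
    marker) by Otsu thresholding with a user background cut-off and pixel-area
    gating; foci are detected inside each retained nucleus with an adaptive
    Gaussian-weighted local threshold and connected-component labeling. Results
    are returned as tidy per-nucleus tables and written as CSV files together
    with diagnostic label and overlay images. A seeded synthetic-scene generator
    produces ground-truthed marker/damage image pairs so the whole pipeline can
    be validated without microscopy data, and a command-line interface drives
    batch runs non-interactively.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jpeg,
    jsonlite,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tiff,
    tools,
    utils
Suggests:
    EBImage,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
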