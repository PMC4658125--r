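Package: drawerseg
Title: Segmentation and Metadata Capture for Multi-Specimen Collection Scans
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for digitising whole-drawer scans and slide-grid scans of
    natural-history collections. Automatically segments a multi-specimen scan
    into per-specimen bounding boxes using an edge-based contour pipeline
    (CIELAB conversion, Gaussian blur, Sobel gradients, recursive contour
    extraction), splits boxes containing several touching specimens with a
    marker-seeded watershed, validates per-specimen metadata against YAML
    templates (including a built-in Simple Darwin Core template), and exports
    full-resolution crops and CSV metadata in unattended batch mode. Includes
    seeded generators of synthetic drawer and slide-grid images with ground
    truth, and a precision/recall scorer for benchmarking segmentation output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    EBImage,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
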