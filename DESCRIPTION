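Package: fluorcount
Title: Zero-Shot Cell Counting for Fluorescence Microscopy Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An annotation-free cell-counting pipeline for fluorescence
    microscopy and immunocytochemistry images. Provides contrast-limited
    adaptive histogram equalization (CLAHE) implemented from first
    principles for illumination correction, a prompt-free instance-mask
    extraction contract with a classical reference backend and an optional
    adapter for pre-trained automatic mask generators, bounding-box
    centroid counting, count-error metrics (mean absolute error and
    acceptable absolute error with density stratification), and a seeded
    synthetic fluorescence image generator with exact ground truth for
    end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    png,
    tiff,
    yaml,
    jsonlite,
    stats,
    utils,
    tools,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
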