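Package: phantomtex
Title: Texture-Feature Robustness Analysis for Phantom MRI Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulates spoiled-gradient-echo MRI series of a multi-tube gel
    phantom under controlled acquisition parameters (field strength, flip
    angle, number of excitations, scanner platform), reads and writes
    single-frame DICOM slices, applies partial-volume correction by iterative
    optimal thresholding and global grayscale normalization, extracts a
    41-feature texture panel (histogram, gray-level co-occurrence matrix,
    gray-level run-length, gray-level gradient, and Laws texture energy
    families), and quantifies feature sensitivity to each acquisition
    parameter with independent-samples tests and Benjamini-Hochberg false
    discovery rate control.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    tools,
    png,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
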