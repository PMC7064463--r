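Package: snbi
Title: Snapshot Narrow-Band Imaging Pipeline for Contrast-Enhanced Tissue Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computational pipeline for snapshot narrow-band imaging (SNBI) of
    hemoglobin-rich lesions. Splits a single raw frame captured through a 2x2
    narrow-band spectral filter mosaic into four co-registered band images,
    normalizes them against dark-current and white-reference-board frames,
    fuses the bands into one contrast-enhanced image, classifies pixels into
    tissue grades from a few manually labeled seed regions with a
    minimum-Euclidean-distance rule, and delineates boundary contours between
    grades. Includes a synthetic cervical-tissue phantom generator so every
    stage is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    png,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
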