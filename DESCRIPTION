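Package: bamotion
Title: Block-Matching Motion Analysis of Beating-Heart Video
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies cardiac tissue motion from grayscale video by dense
    block matching: exhaustive mean-absolute-error search for the integer
    displacement of each pixel block between consecutive frames, region-of-
    interest averaged speed traces, contraction-event detection with duration
    and deformation-distance endpoints, and Welch t-test group comparison.
    Includes a synthetic beating-heart phantom generator with exactly known
    per-frame displacement fields for validation, a minimal uncompressed
    multi-page TIFF reader/writer, CSV/JSON exporters and a command-line
    pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
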