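Package: spondyref
Title: Reference Data and Standardized Scores for Lumbar Disc Metrics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Computes sagittal-plane-offset and disc metrics for lumbar
    intervertebral levels from four-corner vertebral body landmarks, builds
    trimmed level-specific reference statistics (classical and robust), and
    emits standardized scores (Z, robust normalized, and a regression-based
    spondylolisthesis index).  Includes a synthetic landmark-population
    generator for end-to-end validation and a divergent-beam projection
    simulator that quantifies measurement error caused by out-of-plane
    radiographic imaging.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
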