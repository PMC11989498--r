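Package: shadowtex
Title: GLCM Texture Analysis of Posterior Acoustic Shadows in B-Mode Ultrasound
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the texture of posterior acoustic shadows behind
    kidney and gallbladder stones on B-mode ultrasound images using gray
    level co-occurrence matrices (GLCM). Provides region-of-interest patch
    extraction, co-occurrence matrix construction at configurable gray-level
    quantization, offset and symmetry settings, the four classical Haralick
    descriptors (contrast, correlation, energy, homogeneity), per-class
    mean and 95% confidence-interval summaries, and a confidence-band
    separation report that flags which descriptors distinguish
    diagnostic-probability classes. A seeded speckle phantom generator
    produces B-mode-like images with a hyperechoic stone and a tunable
    posterior shadow so the full pipeline can be exercised and tested
    without clinical data.
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
    png,
    tiff,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
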