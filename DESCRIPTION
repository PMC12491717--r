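Package: pelletscope
Title: In-Line Pellet Size and Shape Monitoring from Process Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Machine-vision process analytics for fluid-bed pellet layering:
    generation of annotated synthetic endoscope-like frames of dense
    fluidized pellet flow, classical in-focus instance segmentation with
    confidence filtering, calibrated particle morphometry (equivalent
    circular diameter, circularity, aspect ratio), volume-weighted particle
    size distribution statistics (D10/D50/D90, span), two-sample
    Kolmogorov-Smirnov distribution comparison, rolling in-line D50
    monitoring with endpoint detection, gray-level co-occurrence matrix
    surface texture features, and IoU-based detection-quality evaluation
    (precision, recall, F1, mAP).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    polyclip,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
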