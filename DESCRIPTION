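Package: scrunchr
Title: Quantification and Classification of Planarian Oscillatory Gaits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify planarian locomotor gaits from single-worm
    video recordings or body-length time series. Provides a synthetic
    recording generator with known ground truth (gliding, peristalsis and
    scrunching regimes), image-stack processing (background subtraction,
    segmentation, moment-based ellipse fitting of the worm silhouette),
    oscillation-cycle detection and the four scrunching parameters
    (frequency, maximum elongation, relative speed, fraction of time spent
    elongating), nearest-centroid gait classification against packaged
    reference values with t-test reports, 15-second-interval behavior-score
    aggregation with Fisher's exact window comparisons, and qPCR support
    (primer efficiency from standard curves, delta-delta-Ct knockdown).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
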