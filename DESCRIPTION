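Package: herdmotion
Title: Movement Monitoring Analytics for Group-Housed Pigs from Overhead
    Segmentation Contours
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A detector-agnostic toolkit for quantifying the movement of
    group-housed pigs from per-frame instance-segmentation contours recorded
    by an overhead camera. Each pig contour is condensed to a single centre
    point (spatial image moments of the rasterized contour, plus
    mean-coordinate, iterative least-squares and signed-area centroids for
    comparison), the per-frame centres are merged into one group position by
    agglomerative clustering, and consecutive group positions yield a
    scale-invariant displacement expressed as a percentage of the image
    diagonal. Downstream analytics cover daily and hourly movement
    aggregation, pen occupancy density grids and quadrant statistics, and
    precision/recall/F1 evaluation of detections against reference contours.
    A synthetic pen-scene generator with full ground truth makes every stage
    of the pipeline testable without video data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    optparse,
    jsonlite
Config/testthat/edition: 3
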