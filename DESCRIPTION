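Package: seedpheno
Title: Synthetic Training Data, Detection Metrics and Morphometry for Seed Phenotyping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for image-based seed phenotyping built around a
    domain-randomized compositor: builds background-free seed sprite pools
    (from scans or synthetic fixtures), pastes them with random rotation and
    placement onto virtual canvases under an overlap constraint to produce
    instance-segmentation training data with COCO annotations and 16-bit
    label maps; evaluates predicted instances against ground truth with
    bounding-box and mask IoU, recall and average precision (single and
    swept thresholds); screens segmented instances with margin, solidity
    and length-to-width-ratio quantile filters; and quantifies seed shape
    with eight morphometric descriptors, normalized elliptic Fourier
    descriptors, mean contours and PCA latent-space contour reconstruction.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    png,
    tiff,
    jsonlite,
    tibble,
    dplyr,
    tidyr,
    purrr,
    generics,
    ggplot2,
    rlang,
    stats,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
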