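Package: dafdnet
Title: Direction-Aware Fracture Detection on Radiograph-Like Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detection of thin, low-contrast fracture lines in grayscale
    radiograph-like images with a direction-aware encoder-decoder
    segmentation network. Combines a fixed Gabor wavelet filter bank with
    lightweight ghost convolutions carrying squeeze-and-excitation channel
    attention, trained by mean-squared-error regression against binary
    fracture masks. Includes the two-stage localization-then-detection
    pipeline (femoral-neck region-of-interest segmentation followed by
    fracture-line detection on the crop), region-overlap evaluation
    (bounding-box IOU, mask Dice and Jaccard with binned summaries), and a
    synthetic radiograph phantom generator with paired ground-truth masks
    so the whole system is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    png,
    Rcpp,
    stats,
    tiff,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
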