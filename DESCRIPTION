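Package: wunet
Title: Weighted Attention U-Net Segmentation of Liver Vessels in
    Intraoperative Ultrasound
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: End-to-end pipeline for real-time binary segmentation of
    liver vessels in intraoperative ultrasound (IOUS) video frames using
    a two-input, weight-map-guided attention U-Net.  Includes frame
    quality filtering (black, vessel-absent and blurred frames),
    clip splitting on structural change, patient-level dataset splits,
    a superpixel quadratic-programming saliency prior with max-pooled
    weight-map pyramid, a single-precision convolutional network engine
    with attention-weighted skip gating, a per-vessel training loop with
    strict patient isolation, pixel-wise evaluation metrics (Dice, IoU,
    recall, precision, accuracy, AUC-ROC) aggregated per vessel, and a
    seeded speckle phantom generator that emulates IOUS clips for
    download-free testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    EBImage,
    png,
    yaml,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    tiff,
    pROC,
    withr
Config/testthat/edition: 3
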