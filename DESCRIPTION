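Package: slideseg
Title: Desk-Scale Whole-Slide Image Segmentation Toolkit
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tiled semantic segmentation of pyramidal whole-slide histology
    images on a single workstation. Provides on-the-fly class-balanced
    training-patch streaming, deterministic overlapping-grid inference with
    logit averaging and border trimming, conversion between label masks,
    Aperio ImageScope style XML contours and a JSON annotation/heatmap
    schema, object-level morphometric feature extraction (including percent
    interstitial fibrosis and tubular atrophy), and segmentation evaluation
    (Matthews correlation, F-score, Cohen's kappa, ROC/AUC from stitched
    logits, intraclass correlation, and UMAP+KNN class separability). A
    seeded synthetic-slide generator emulating stained tissue on a white
    background lets every stage run without external slide data, and a small
    reference patch segmenter exercises the full train/predict pipeline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    png,
    xml2,
    jsonlite,
    pROC,
    uwot,
    class,
    tibble,
    stats,
    utils,
    tools,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
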