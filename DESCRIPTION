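Package: phagoscope
Title: Quantitative Analysis of Tandem-Reporter Autophagy Time-Lapse Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying autophagy in tandem mRFP-EGFP reporter
    time-lapse fluorescence microscopy. Provides a seeded synthetic-data
    generator emulating five-frame, three-channel sequences of cells with
    yellow (autophagosome) and red-only (autolysosome) puncta and full ground
    truth; readers and writers for per-channel TIFF images, per-cell masks,
    bounding boxes (CSV and YOLO dialects) and class labels; a classical
    reference detector and standard detection/segmentation metrology
    (IoU, COCO-style mAP50 and mAP50-95, pixel precision/recall/F1/accuracy);
    red-channel spot segmentation with replicate normalization and a
    percentile-based activation threshold classifier plus confusion-matrix
    metrics including the multiclass Matthews correlation coefficient; a
    feature-based multi-object cell tracker using Hungarian assignment with
    an active/inactive track lifecycle, re-identification and division
    handling, with track-quality metrics; transition summaries, occlusion
    saliency maps, and an end-to-end deterministic pipeline with a
    command-line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    png,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
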