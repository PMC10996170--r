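Package: pfmus
Title: Automatic Evaluation of Pelvic Floor Muscle Contraction from
    Bladder Ultrasound Video
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for automatic classification of pelvic floor muscle
    (PFM) contraction from transabdominal B-mode bladder ultrasound
    video, intended as the analysis engine of a PFM training biofeedback
    system. The package segments the anechoic bladder region in each
    frame, extracts five geometric landmarks (the endpoints and midpoint
    of the maximum bladder diameter and the vertical extents of the
    bladder wall through that midpoint), assembles stride-sampled
    coordinate time series per contraction clip, computes a fixed
    catalogue of time-series features (moments, peak counts, FFT
    coefficients) together with a bladder-area surrogate and the bladder
    base elevation, and runs a supervised four-class protocol
    (train/test split, five-fold cross-validated model comparison, grid
    search tuning, held-out evaluation with one-vs-rest AUC, feature
    importance ranking). A seeded synthetic ultrasound generator with
    class-specific bladder motion and ground-truth geometry supports
    testing and method development in the absence of patient recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    EBImage,
    xgboost,
    ranger,
    nnet,
    pROC,
    jsonlite,
    yaml,
    tiff,
    withr
Suggests:
    testthat (>= 3.0.0),
    pracma
Config/testthat/edition: 3
RoxygenNote: 7.3.3
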