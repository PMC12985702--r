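Package: endobleed
Title: Weakly Supervised Detection and Quantification of Intraoperative
    Bleeding in Endoscopic Video
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-stage pipeline for segmenting and quantifying intraoperative
    bleeding in endoscopic surgical video. A base segmentation network is
    trained on weak labels produced by HSV colour thresholding of red regions
    within the endoscopic field of view, then fine-tuned on a small curated
    set in which red distractors (vessels, cancellous bone) carry all-negative
    "zero masks" so the model learns to suppress them. Includes a seeded
    synthetic endoscopic scene generator with per-component truth masks and
    simulated annotators, a multi-rater evaluation suite (Dice/IoU, consensus
    panel selection, agreement and bleeding-area stratification, Wilson and
    Clopper-Pearson intervals, Spearman correlation, pixel-wise
    precision-recall), and frame-by-frame video bleeding-area-ratio
    quantification with composite rendering.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    EBImage,
    png,
    jsonlite,
    yaml,
    stats,
    grDevices,
    tools,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
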