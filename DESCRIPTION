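Package: cytoscreen
Title: Progressive Multi-Resolution Screening of Cervical Cytology Whole-Slide Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale implementation of a progressive whole-slide-image (WSI)
    screening system for cervical cytology. A low-resolution model scans
    overlapping 512-pixel tiles (0.486 um/px) and emits a lesion probability plus
    a location heatmap; tiles passing a 0.5 probability gate are refined by a
    high-resolution model on 256-pixel crops (0.243 um/px) that confirms
    candidates and extracts feature vectors; the rank-ordered top-k candidate
    features feed a six-member recurrent-network ensemble (k = 10, 20, 30, two
    members each) that scores slide positivity. Includes a multi-style synthetic
    slide generator with exact point ground truth, HSV-space photometric
    augmentation, group- and category-balanced sampling with two-round hard-sample
    mining, duplicate suppression and top-k ranking, and a screening evaluation
    toolkit (ROC/AUC, sensitivity/specificity, specificity at full sensitivity,
    top-k true positive rate, slide-score histograms).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    EBImage,
    tiff,
    png,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
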