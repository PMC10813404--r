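Package: fundusHR
Title: Hypertensive Retinopathy Grading from Retinal Fundus Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Toolkit for automated hypertensive retinopathy (HR) analysis of
    color fundus photographs. Implements a bespoke contrast-enhancement chain
    (per-channel Gaussian gain, HSV transform, Doane-based normalization and
    probability-threshold channel selection), a lightweight vessel-segmentation
    network built around a spatial-convolution attention block with pyramid
    pooling, k-means optic-disc removal, a 24-feature vessel descriptor
    (texture, color, disc and vascular groups), boosted SVM and KNN grade
    classifiers with k-fold cross-validation, and the six evaluation metrics
    used for HR studies. A built-in synthetic fundus generator renders
    grade-dependent findings (arteriolar narrowing, focal constriction,
    hemorrhages, hard exudates, disc edema) with pixel-accurate ground truth
    so that every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    EBImage,
    e1071,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: ImageProcessing, Classification, Visualization
RoxygenNote: 7.3.3
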