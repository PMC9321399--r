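Package: tnfresponse
Title: Anti-TNF Treatment Response Prediction from Plasma Proteomics
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for predicting response to anti-TNF therapy in rheumatoid
    arthritis from targeted plasma proteomics (Olink-style NPX data).
    Implements NPX quality control, below-LoD masking, k-nearest-neighbour
    imputation and per-protein standardisation; resampling-based feature
    importance with elastic-net logistic regression; nested cross-validated
    stepwise model selection with Youden-index thresholding; a packaged
    published 17-protein linear scorer with logistic probability mapping;
    PCA-based endotype discovery with leave-one-out PRESS; and a synthetic
    cohort generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
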