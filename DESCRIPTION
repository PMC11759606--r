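Package: pathomil
Title: Weakly Supervised Pathomics for Metastasis and Survival Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A weakly supervised multiple-instance-learning pipeline for
    haematoxylin-and-eosin whole-slide images: non-overlapping tiling with
    white-background exclusion and Reinhard colour normalization in Ruderman
    lab space, a patch-level classifier trained with slide-inherited (weak)
    labels under SGD, softmax cross-entropy and a cosine-decay learning rate,
    slide-level feature fusion by patch-likelihood histograms and TF-IDF
    bag-of-words (206 named features per slide), Pearson-redundancy feature
    filtering, metastasis classification with a full metric panel, and
    L2-penalized Cox survival modelling with Kaplan-Meier percentile
    stratification and a nomogram. A synthetic-slide generator with planted
    signal makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    png,
    jsonlite,
    withr,
    survival,
    randomForest,
    xgboost,
    glmnet,
    pROC
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
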