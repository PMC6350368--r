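Package: mirwalkreg
Title: miRNA-Disease Association Prediction by Network Random Walk and
    Logistic Regression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts candidate miRNA-disease associations by combining
    network propagation with a per-disease classifier. miRNAs are embedded
    in an integrated similarity network (curated functional similarity where
    available, Gaussian interaction-profile kernel similarity elsewhere); a
    random walk with restart from every miRNA yields stationary proximity
    profiles; for each disease, the stationary mass of each miRNA's top-K
    walk neighbours is split by association label into a ternary feature
    vector, and a binary logistic regression fitted by maximum likelihood
    scores the unlabelled miRNAs. Includes leave-one-out cross-validation
    with rank-pooled ROC/AUC, a planted-block synthetic data generator, and
    tidy accessors for all result types.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
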