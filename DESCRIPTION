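Package: dermalo
Title: Dermoscopy Lesion Enhancement, Feature Fusion and Antlion-Optimized
    Feature Selection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Toolkit for multiclass skin-lesion classification pipelines on
    dermoscopy images. Implements hybrid contrast enhancement combining
    dark-channel-prior haze reduction with top-hat/bottom-hat morphological
    filtering, serial correlation-based fusion of multi-extractor feature
    tables, wrapper feature selection with an antlion optimizer extended by a
    mean-deviation re-seeding step (ALO-MD), genetic-algorithm hyperparameter
    tuning, and a multiclass cross-validation harness reporting accuracy,
    macro sensitivity/precision/F1, FNR, AUC, Fowlkes-Mallows index, MCC and
    Cohen's kappa. Ships synthetic fixture generators (hazy lesion-like
    images, labelled feature tables with known informative/noise/redundant
    structure) so every stage is testable without external datasets, plus an
    end-to-end pipeline driver and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    class,
    rpart,
    nnet,
    e1071,
    randomForest,
    png,
    jsonlite,
    pROC
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
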