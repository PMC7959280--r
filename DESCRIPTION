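Package: gesturenet
Title: Surgical Gesture Classification from EEG Functional Brain Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A pipeline for classifying robot-assisted surgical hand gestures
    from multichannel EEG. Builds windowed magnitude-squared-coherence
    functional connectivity networks, detects time-varying community structure
    with multilayer modularity optimization and consensus clustering, and
    extracts 60 dynamic network and spectral-power features per gesture epoch
    (flexibility, integration, recruitment, search information, strength,
    diffusion efficiency, transitivity, global efficiency, and band power per
    cortical subsystem). Features feed an imbalance-aware evaluation protocol:
    SMOTE oversampling inside training folds, ANOVA F feature selection,
    k-nearest-neighbour and tree-ensemble classifiers, stratified 10-fold
    cross-validation, and paired t-tests with Bonferroni correction. Includes
    a synthetic EEG generator with planted, class-conditional coherence and
    power structure for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    igraph,
    ranger,
    class,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse
Config/testthat/edition: 3
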