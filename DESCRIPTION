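Package: bcibench
Title: Benchmarking Framework for Sensory-Motor Brain-Computer Interfaces
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for comparing classifiers in sensory-motor
    EEG brain-computer interfaces. Provides Butterworth filter-bank
    preprocessing, Common Spatial Patterns (CSP) spatial filtering, band-power
    and Morlet-wavelet feature extraction, a uniform train/predict-probability
    contract over seven standard classifiers with joint model selection by
    repeated stratified cross-validation, synchronous (accuracy) and self-paced
    (sliding-window AUC) evaluation, and a rank-based statistics layer
    (Friedman test with Holm step-down post-hoc and recommended-set
    partitioning). A synthetic EEG generator with controllable class-dependent
    event-related desynchronization makes every stage testable without access
    to recorded data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    MASS,
    glmnet,
    randomForest,
    e1071,
    rpart,
    rhdf5,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    signal,
    pROC,
    optparse
Config/testthat/edition: 3
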