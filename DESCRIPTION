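Package: cardiomech
Title: Aortic-Stenosis Screening from Chest-Worn Inertial Cardiomechanical Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An end-to-end analysis toolkit for detecting aortic stenosis from
    seismocardiogram (SCG, 3-axis accelerometer) and gyrocardiogram (GCG,
    3-axis gyroscope) recordings taken on the sternum, without any reference
    ECG. Provides artifact-robust preprocessing (band-pass filtering, sliding
    RMS motion-artifact masking, fixed-length chunking), heartbeat detection
    from the fused Hilbert envelopes of the linear and angular resultant
    signals, per-beat GCG fiducial annotation (A, I, J, K, L, plus the
    maximum-acceleration point P and its amplitude MA), a feature space of
    time-domain HRV, frequency-domain HRV, and GCG timing-interval statistics,
    classifier training with cross-validated hyperparameter search and
    Gaussian-process Bayesian optimization of the filter parameters, and
    exact-enumeration Shapley feature attribution. A fully seeded synthetic
    cardiomechanical signal generator with per-beat ground truth makes every
    pipeline stage testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    purrr,
    ranger,
    readr,
    rlang,
    rpart,
    lhs,
    stats,
    tibble,
    tidyr,
    utils,
    signal,
    xgboost,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
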