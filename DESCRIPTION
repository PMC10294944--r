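Package: ctgnet
Title: Deep Learning Classification of Early-Labour Cardiotocograms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end pipeline for classifying 20-minute early-labour
    fetal heart rate (FHR) recordings into severe-compromise versus
    no-compromise births. Provides a synthetic cardiotocogram simulator
    (baseline drift, short-term variability, accelerations and
    decelerations, sensor dropout, maternal-heart-rate capture artifacts),
    two-stage signal cleaning and quality-controlled 20-minute segment
    extraction, linear / autoregressive / Gaussian-process gap imputation,
    spectrogram and wavelet-scalogram time-frequency images, positive-class
    augmentation by overlapping windows and oversampling, five 1D-CNN /
    LSTM / residual 2D-CNN network architectures trained with weighted
    binary cross-entropy, partial-AUC evaluation at low false-positive
    rates, and post-hoc attribution of predictions to signal loss and
    clinical FHR features (short-term variability and baseline).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    signal,
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'zzz.R'
    'AllClasses.R'
    'AllGenerics.R'
    'simulate.R'
    'preprocess.R'
    'impute.R'
    'timefreq.R'
    'augment.R'
    'nn.R'
    'models.R'
    'metrics.R'
    'train.R'
    'posthoc.R'
    'io.R'
    'pipeline.R'
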