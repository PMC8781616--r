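Package: ecghht
Title: Hilbert-Huang ECG Features and Hybrid Arrhythmia Pattern Recognition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Recognition of hybrid arrhythmia patterns (atrial premature
    complex, atrial fibrillation, ventricular premature complex,
    ventricular tachycardia) against normal sinus rhythm from single-lead
    ECG. Frames of the signal are low-pass filtered, decomposed by
    empirical mode decomposition, and summarised by the area centroids
    (mean frequency and power) of the marginal Hilbert spectrum of the
    first three intrinsic mode functions. A coupled bank of four
    classifiers (multilayer perceptron, boosted decision-tree ensemble,
    support vector machine, Gaussian naive Bayes) with one-versus-one
    multiclass coding is trained on observed or Gaussian-simulated
    feature tables, evaluated with ROC/AUC and stratified
    cross-validation, and applied to whole records by a sliding-window
    scanner that emits traceable per-frame symptom labels. A synthetic
    module generates both feature-space Gaussian data sets and
    waveform-level ECG fixtures for the five rhythm classes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    nnet,
    pROC,
    randomForest,
    rpart,
    signal,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
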