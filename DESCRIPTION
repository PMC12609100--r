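Package: PulseAAA
Title: In Silico Abdominal Aortic Aneurysm Diagnosis from Arterial Pulse Waveforms
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Simulates arterial blood-pressure and cuff pulse-volume-recording
    (PVR) waveforms across a synthetic cohort with graded abdominal aortic
    aneurysm (AAA) severity, using a 55-segment linear transmission-line model
    of the systemic arterial circulation with three-element Windkessel terminal
    loads and viscoelastic artery-tissue-cuff transfer functions. Provides
    AAA-sensitive waveform features (carotid-femoral pulse wave velocity,
    carotid upstroke index, carotid area ratio, carotid oscillatory ratio), a
    volumetric severity index (VSI) parameterisation of the aneurysm, and a
    one-dimensional convolutional network with continuous property-adversarial
    regularization (CPAR) that estimates VSI from brachial and tibial waveforms
    while remaining uninformative about subject height and age. Includes
    threshold-swept detection metrics and ROC/PRC evaluation utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    Rcpp,
    stats,
    utils,
    yaml,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    pROC,
    optparse
LinkingTo: Rcpp
Config/testthat/edition: 3
biocViews: Software, Regression, Classification, FeatureExtraction
RoxygenNote: 7.3.3
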