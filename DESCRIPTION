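Package: odnn
Title: All-Optical Diffractive Neural Network Simulation for Pulmonary
    Nodule Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates all-optical diffractive deep neural networks (D2NN):
    scalar free-space propagation by the band-limited angular spectrum method
    with a direct Rayleigh-Sommerfeld summation oracle, stacks of trainable
    per-pixel phase/amplitude masks, detector-region readout, and gradient
    training of the masks by backpropagation through the optical forward
    model.  Includes the detection and benign/malignant classification
    workflows for pulmonary nodules on CT-like images: sliding-window slice
    scanning, readout normalizations and losses, case-level data splitting
    and cross-validation, binary classification metrics (F1, MCC, ROC/AUC),
    and seeded synthetic CT-like patch and slice generators so the whole
    pipeline runs without any external imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    png
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
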