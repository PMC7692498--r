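Package: qrsvalid
Title: Heartbeat Segmentation with a CNN Validator for QRS Detections
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for single-lead ECG heartbeat segmentation built around a
    two-stage design: a classic Pan-Tompkins adaptive-threshold R-peak
    detector whose candidate detections are then accepted or rejected by a
    small one-dimensional convolutional network trained on beat morphology.
    Includes a synthetic ECG generator with P/Q/R/S/T fiducial waves and
    standard noise models, readers for WFDB and plain CSV records with beat
    annotations, the shift/attenuation data-augmentation scheme that expands
    each annotated beat into eleven labelled training windows plus strided
    between-beat negative windows, a from-scratch CNN (SGD with momentum,
    staged learning-rate schedule), and a tolerance-based evaluation pipeline
    reporting sensitivity, positive predictivity and F-score for raw versus
    validated detections.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    pracma,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
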