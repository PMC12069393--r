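Package: cvdmix
Title: Token-Mixer Transformer Classification of Cardiovascular Disease from ECG Features
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for four-class cardiovascular disease
    classification (arrhythmia, atrial fibrillation, congestive heart failure,
    normal sinus rhythm) from single-lead ECG. Implements zero-phase Butterworth
    band-pass preprocessing, the maximal-overlap discrete wavelet packet
    transform (MODWPT) with symlet filters for R-peak detection and
    moving-window delineation of P-QRS-T fiducial points, a 54-feature registry
    (morphological, fiducial, statistical and heart-rate-variability features),
    random-forest out-of-bag permutation feature importance with threshold
    selection, serialization of selected features to text with WordPiece-style
    tokenization, and a token-mixer transformer classifier (multi-head
    self-attention followed by a short-time aggregation convolution) trained
    with AdamW. Includes a synthetic ECG and feature-table generator with
    ground-truth annotations, a multiclass evaluation suite (confusion matrix,
    per-class and macro metrics, one-vs-rest ROC/AUC), and a reproducible
    pipeline orchestrator.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    randomForest,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
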