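Package: mrecg
Title: Multirate ECG Processing and Arrhythmia Classification
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: A multirate processing chain for single-lead electrocardiogram
    (ECG) beat classification. Implements band-pass linear-phase FIR
    denoising, aliasing-safe decimation, fixed-window segmentation, a
    three-level Daubechies wavelet filter bank, per-subband statistical
    feature extraction (energy, kurtosis, peak values), k-nearest-neighbor
    classification with stratified cross-validation, and the compression and
    computational-cost accounting used to compare multirate and fixed-rate
    front ends. Includes a seeded generator of synthetic three-class ECG
    beats (normal sinus rhythm, right bundle branch block,
    Wolff-Parkinson-White) with power-line interference, baseline wander and
    white-noise contamination, so the whole chain runs without external
    recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    signal,
    stats,
    tools,
    utils
Suggests:
    e1071,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
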