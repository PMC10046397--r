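Package: ppgbp
Title: Cuffless Blood Pressure Estimation from Photoplethysmography with
    Gaussian-Process Regression and ISO 81060-2 Validation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating systolic and diastolic blood pressure from
    single-channel reflective photoplethysmography (PPG). Provides a synthetic
    PPG generator with known ground-truth blood pressure and graded signal
    quality, AC/DC decomposition and pulse segmentation, extraction of a
    ten-dimensional waveform feature vector per 15-second window,
    exponential-kernel Gaussian-process regression with a fixed-hyperparameter
    fine-tuning scheme, cuff-reference calibration, the same-arm sequential
    measurement protocol, and the full validation toolkit (ISO 81060-2
    criteria 1 and 2, British Hypertension Society grading, Bland-Altman
    limits of agreement, Pearson correlation).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    pracma,
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
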