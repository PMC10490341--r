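Package: ppgbp
Title: Cuffless Blood-Pressure Estimation from Photoplethysmogram Waveforms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A beat-level pipeline for estimating systolic and diastolic blood
    pressure from the photoplethysmogram (PPG) across rest, exercise and
    recovery. Provides per-beat quality screening with the skewness signal
    quality index (SSQI), detection of PPG and second-derivative (SDPPG a-e
    wave) fiducial points, extraction of 17 morphological features, RReliefF
    feature selection with negative-score elimination, a bidirectional LSTM
    sequence regressor trained on sliding beat windows, and agreement analysis
    (MAE/ME/RMSE, Bland-Altman limits, the ISO 81060-2 accuracy criterion).
    A protocol-faithful synthetic PPG+BP generator with known ground truth
    makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    pracma,
    signal,
    e1071,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    knitr
Config/testthat/edition: 3
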