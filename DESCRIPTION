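Package: vrstress
Title: Rule-Based Stress Detection from VR Behavioral Telemetry and
    Galvanic Skin Response
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects user stress in virtual-reality sessions by fusing four
    binary behavioral indicators (hesitation, repeated errors, inactivity,
    controller tremor) with a galvanic skin response (GSR) slope detector.
    Implements the weighted rule Sf = alpha*Sb + beta*Sp, a three-tier online
    decision logic with selective behavioral/physiological fusion, a
    nearest-centroid three-class stress classifier, a calibrated synthetic
    session simulator (truncated-normal marginals coupled through a latent
    arousal factor), evaluation utilities (confusion matrices, one-vs-rest
    ROC/AUC, Pearson correlation), and an adapter for WESAD-style wearable
    recordings (wrist EDA plus heart rate estimated from blood volume pulse).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    optparse,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
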