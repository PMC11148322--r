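Package: mmbulbar
Title: Multimodal Assessment of Bulbar Motor Involvement from Facial sEMG
    and Speech Acoustics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Automated extraction of 60 neuromuscular and acoustic features
    spanning seven constructs of bulbar/speech motor control (prosody, pause,
    functional connectivity, amplitude, rhythm, complexity, regularity) from
    synchronized speech audio and three-channel facial surface
    electromyography, together with the statistical validation layer used to
    turn those features into composite outcome measures: Cohen's d effect-size
    screening, confirmatory factor analysis with Bartlett factor scores,
    Cronbach's alpha reliability, repeated cross-validated machine-learning
    regression and classification, and summary-statistic group tests.
    Includes seeded synthetic-signal generators (speech-like audio with known
    pause schedule, fundamental-frequency contour and theta-rate amplitude
    modulation; bursting sEMG with a controllable shared oscillatory drive)
    so that every stage of the pipeline can be exercised against known ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    randomForest,
    e1071,
    pROC,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
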