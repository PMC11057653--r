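Package: SleepStaging
Title: Sleep-Stage Prediction from Wearable Heart-Rate and Activity Streams
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for four-class sleep staging (wake, light,
    deep, REM) from consumer wearable data. Provides a calibrated
    semi-Markov generator of labeled synthetic nights (hypnogram,
    stage-conditional heart rate, steps, acceleration, and overlapping
    short/long summary records), interval-record preprocessing (expansion
    to an epoch grid, short-wins de-duplication, floor alignment, natural
    joins into named instance schemas), engineered features (cosine clock,
    a light-entrained van der Pol circadian oscillator, activity counts,
    Gaussian and difference-of-Gaussians smoothing, heart-rate variation,
    log-positivity and min-max transforms), sliding-window sequence
    construction, a suite of memoryless classifiers plus a
    from-first-principles LSTM trained by backpropagation through time,
    and weighted multiclass evaluation including Cohen's kappa and the
    Matthews coefficient, with a memory-step sweep.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    deSolve,
    nnet,
    class,
    e1071,
    randomForest
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
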