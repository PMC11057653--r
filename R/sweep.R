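## Memory-step sweep: how far back to look before predicting. For each ns
## the table is windowed, split, a model trained and scored; the summary
## identifies the first ns attaining the maximum accuracy.

#' Sweep over memory steps
#'
#' For each `ns` in `nsValues`: build windows, make a stratified 0.75/0.25
#' split, train the requested model, and score the held-out sequences.
#'
#' @param table labeled feature table ([EpochTable-class] or `data.frame`
#'   with `time` and `stage`).
#' @param nsValues integer vector of history steps to try.
#' @param model `"LSTM"` or a memoryless engine name
#'   (`"RF"`, `"LR"`, `"kNN"`, `"SVM"`, `"MLP"`).
#' @param config [trainConfig()] list for the LSTM (ignored otherwise).
#' @param grid hyper-parameter grid for memoryless engines.
#' @param trainFraction train split fraction.
#' @param seed integer seed (split and training).
#' @param featureCols feature columns passed to [makeWindows()].
#' @param interval grid interval for gap detection on plain frames.
#' @return list with `reports` (one [EvalReport-class] per ns) and
#'   `summary` ([sweepSummary()] output incl. `bestNs`).
#' @export
memorySweep <- function(table, nsValues, model = "LSTM",
                        config = trainConfig(), grid = NULL,
                        trainFraction = 0.75, seed = 1L,
                        featureCols = NULL, interval = NULL) {
  reports <- lapply(nsValues, function(ns) {
    ds <- makeWindows(table, ns, featureCols = featureCols,
                      interval = interval)
    sp <- splitData(ds, trainFraction, seed = seed)
    if (identical(model, "LSTM")) {
      cfg <- config; cfg$seed <- as.integer(seed)
      fit <- trainLSTM(sp$train, cfg)
      pred <- predict(fit, sp$test)
      probs <- predict(fit, sp$test, type = "prob")
      scoreClassifier(sp$test@labels, pred, probabilities = probs,
                      metadata = list(model = model, ns = ns, seed = seed))
    } else {
      ftr <- flattenWindows(sp$train); fte <- flattenWindows(sp$test)
      fit <- fitMemoryless(ftr$x, ftr$y, engine = model, grid = grid,
                           seed = seed)
      pred <- predict(fit, fte$x)
      scoreClassifier(fte$y, pred,
                      metadata = list(model = model, ns = ns, seed = seed))
    }
  })
  list(reports = reports, summary = sweepSummary(reports))
}

#' Predict a full night's hypnogram with a trained model
#'
#' Rolling per-epoch prediction over a night: windows are built at the
#' model's history depth and the predicted stage sequence is re-aligned to
#' the night's grid (the first `ns` epochs, which lack a full history,
#' repeat the first prediction so the result is comparable epoch-by-epoch
#' with the true hypnogram).
#'
#' @param model an [LSTMModel-class] or [MemorylessModel-class].
#' @param night an [EpochTable-class] carrying the model's features and a
#'   `stage` column (used only for alignment, not for prediction).
#' @param ns history steps; defaults to the LSTM's trained depth, required
#'   for memoryless models trained on flattened windows with `ns > 0`.
#' @param featureCols feature columns used at training time.
#' @return an [EpochTable-class] with a predicted `stage` column on the
#'   night's grid.
#' @export
predictSequence <- function(model, night, ns = NULL, featureCols = NULL) {
  stopifnot(is(night, "EpochTable"))
  if (is.null(ns))
    ns <- if (is(model, "LSTMModel")) model@ns else 0L
  ds <- makeWindows(night, ns, featureCols = featureCols)
  pred <- if (is(model, "LSTMModel")) predict(model, ds)
          else predict(model, flattenWindows(ds)$x)
  pred <- as.character(pred)
  full <- c(rep(pred[1], ns), pred)
  stopifnot(length(full) == nEpochs(night))
  EpochTable(epochTimestamps(night), epochInterval(night),
             data.frame(stage = full))
}
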