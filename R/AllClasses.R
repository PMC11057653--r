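#' @import methods
#' @importFrom stats approx approxfun rnorm runif rbinom rpois sd median
#'   quantile setNames aggregate cor predict
#' @importFrom utils head tail read.csv write.csv
NULL

## Central container: a uniformly gridded, timestamp-indexed multichannel table.
## All pipeline stages exchange EpochTable objects (hypnograms, signal tables,
## joined instances), mirroring how epoch-scored wearable exports look on disk.

#' EpochTable: a uniformly gridded multichannel epoch table
#'
#' The universal intermediate of the pipeline: a set of strictly increasing,
#' uniformly spaced timestamps (the epoch grid) with named data columns
#' (numeric signals or a factor/character `stage` column), plus the epoch
#' interval in seconds and an optional instance schema identifier.
#'
#' @slot timestamps `POSIXct` vector, strictly increasing, uniformly spaced.
#' @slot interval epoch length in seconds (one of 15, 30, 60 in practice).
#' @slot data `data.frame` with one row per epoch.
#' @slot schemaId optional instance-schema name (`NA_character_` if unset).
#'
#' @examples
#' et <- EpochTable(
#'   timestamps = as.POSIXct("2021-12-16 06:37:00", tz = "UTC") + seq(0, 90, 30),
#'   interval = 30,
#'   data = data.frame(stage = c("light", "light", "wake", "wake"))
#' )
#' nEpochs(et)
#' @export
setClass("EpochTable",
  representation(
    timestamps = "POSIXct",
    interval   = "numeric",
    data       = "data.frame",
    schemaId   = "character"
  ),
  prototype(schemaId = NA_character_)
)

setValidity("EpochTable", function(object) {
  msgs <- character()
  n <- length(object@timestamps)
  if (nrow(object@data) != n)
    msgs <- c(msgs, "data must have one row per timestamp")
  if (length(object@interval) != 1L || !is.finite(object@interval) ||
      object@interval <= 0)
    msgs <- c(msgs, "interval must be a single positive number")
  if (n > 1L) {
    d <- diff(as.numeric(object@timestamps))
    if (any(d <= 0)) msgs <- c(msgs, "timestamps must be strictly increasing")
    ## uniform spacing equal to the declared interval (gap-free grid)
    if (any(abs(d - object@interval) > 1e-6))
      msgs <- c(msgs, "timestamps must be uniformly spaced at `interval` seconds")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct an EpochTable
#'
#' @param timestamps `POSIXct` epoch start times (strictly increasing, uniform).
#' @param interval epoch length, seconds.
#' @param data `data.frame` of per-epoch columns.
#' @param schemaId optional instance schema name.
#' @return An [EpochTable-class] object.
#' @export
EpochTable <- function(timestamps, interval, data, schemaId = NA_character_) {
  new("EpochTable",
      timestamps = as.POSIXct(timestamps, tz = "UTC"),
      interval = as.numeric(interval),
      data = as.data.frame(data),
      schemaId = as.character(schemaId))
}

#' Generator configuration for synthetic wearable nights
#'
#' Holds every knob of the synthetic-night generator. Defaults encode the
#' sleep architecture the pipeline assumes: 4-6 cycles of about 90 minutes
#' with the first cycle shortest, stage dwell-time ranges N1 1-5, N2 10-60,
#' N3 20-40 and REM 10-60 minutes, and long-run stage proportions of
#' wake 12.2%, light 50.1%, deep 18.1%, REM 19.6%.
#'
#' @slot nightLength night length in minutes (soft target; cycles emerge).
#' @slot epochInterval epoch length, seconds; one of 15, 30, 60.
#' @slot nCyclesRange integer pair, inclusive range of sleep cycles per night.
#' @slot cycleLengthMean mean sleep-cycle length, minutes.
#' @slot dwellRanges named list of 2-vectors (minutes) for N1, N2, N3, REM.
#' @slot targetProportions named numeric, long-run epoch fractions for
#'   wake/light/deep/REM; sums to 1.
#' @slot hrEmission named list of `c(mean, sd)` in beats/min per stage.
#' @slot stepEmission named numeric, per-stage rate of nonzero-step epochs.
#' @slot accelNoiseSd accelerometer noise sd, g units.
#' @slot accelFs accelerometer sampling rate, Hz.
#' @slot historyDependence logical; `TRUE` = dwell-time-constrained
#'   semi-Markov cycle model (history informative), `FALSE` = memoryless
#'   first-order chain with the same stationary proportions.
#' @export
setClass("GeneratorConfig",
  representation(
    nightLength       = "numeric",
    epochInterval     = "numeric",
    nCyclesRange      = "integer",
    cycleLengthMean   = "numeric",
    dwellRanges       = "list",
    targetProportions = "numeric",
    hrEmission        = "list",
    stepEmission      = "numeric",
    accelNoiseSd      = "numeric",
    accelFs           = "numeric",
    historyDependence = "logical"
  )
)

setValidity("GeneratorConfig", function(object) {
  msgs <- character()
  if (!object@epochInterval %in% c(15, 30, 60))
    msgs <- c(msgs, "epochInterval must be one of 15, 30, 60 seconds")
  if (60 %% object@epochInterval != 0)
    msgs <- c(msgs, "epochInterval must divide 60")
  if (length(object@nCyclesRange) != 2L ||
      object@nCyclesRange[1] > object@nCyclesRange[2] ||
      object@nCyclesRange[1] < 1L)
    msgs <- c(msgs, "nCyclesRange must be an increasing positive integer pair")
  dr <- object@dwellRanges
  if (!all(c("N1", "N2", "N3", "REM") %in% names(dr)))
    msgs <- c(msgs, "dwellRanges must name N1, N2, N3, REM")
  else if (any(vapply(dr, function(r) any(r <= 0) || r[1] > r[2], logical(1))))
    msgs <- c(msgs, "dwell ranges must be positive increasing pairs")
  tp <- object@targetProportions
  if (!all(c("wake", "light", "deep", "REM") %in% names(tp)))
    msgs <- c(msgs, "targetProportions must name wake, light, deep, REM")
  else if (abs(sum(tp) - 1) > 1e-9)
    msgs <- c(msgs, "targetProportions must sum to 1")
  if (length(msgs)) msgs else TRUE
})

#' Light-entrained circadian oscillator parameters
#'
#' Parameters of the coupled van der Pol circadian pacemaker
#' `dx/dt = pi/12 (x_c + B)`,
#' `dx_c/dt = pi/12 [ mu (x_c - 4 x_c^3 / 3) - x (24 / (0.99669 tau_x))^2 + k_B B ]`
#' plus the Process-L light transduction producing the drive `B` from lux:
#' `alpha(I) = alpha0 (I/I0)^p`, `dn/dt = 60 [alpha(I)(1-n) - beta n]`,
#' `B = G alpha(I) (1-n) (1 - 0.4 x)(1 - 0.4 x_c)`.
#'
#' @slot mu stiffness of the cubic van der Pol term (dimensionless, 0.23).
#' @slot tauX intrinsic oscillator period, hours (24.2).
#' @slot kB direct-light coupling gain in the `x_c` equation.
#' @slot lightGain Process-L drive gain `G`.
#' @slot alpha0 Process-L activation rate scale, per minute.
#' @slot beta decay rate of the activated photoreceptor pool, per minute.
#' @slot i0 reference light intensity, lux.
#' @slot pExp saturation exponent of the light response.
#' @export
setClass("CircadianParams",
  representation(
    mu = "numeric", tauX = "numeric", kB = "numeric",
    lightGain = "numeric", alpha0 = "numeric", beta = "numeric",
    i0 = "numeric", pExp = "numeric"
  )
)

setValidity("CircadianParams", function(object) {
  msgs <- character()
  if (object@mu <= 0) msgs <- c(msgs, "mu must be > 0")
  if (object@tauX <= 0) msgs <- c(msgs, "tauX must be > 0")
  if (length(msgs)) msgs else TRUE
})

#' Sliding-window sequence dataset
#'
#' Sequences of `ns + 1` consecutive feature rows whose label is the stage of
#' the terminal row. Stored as a 3-d array `(sequence, step, feature)`; step
#' `ns + 1` is the current row, step 1 the oldest history row.
#'
#' @slot ns integer, number of history steps (0 = memoryless rows).
#' @slot sequences numeric array, `n x (ns+1) x F`.
#' @slot labels factor of length `n`, stage of each terminal row.
#' @slot featureNames character of length `F`.
#' @export
setClass("WindowedDataset",
  representation(
    ns = "integer",
    sequences = "array",
    labels = "factor",
    featureNames = "character"
  )
)

setValidity("WindowedDataset", function(object) {
  msgs <- character()
  d <- dim(object@sequences)
  if (length(d) != 3L) msgs <- c(msgs, "sequences must be a 3-d array")
  else {
    if (d[2] != object@ns + 1L)
      msgs <- c(msgs, "second dimension must equal ns + 1")
    if (d[1] != length(object@labels))
      msgs <- c(msgs, "labels must match the number of sequences")
    if (d[3] != length(object@featureNames))
      msgs <- c(msgs, "featureNames must match the feature dimension")
  }
  if (length(msgs)) msgs else TRUE
})

#' Fitted memoryless classifier
#'
#' Wraps one of the supported engines (LR, RF, kNN, SVM, MLP) together with
#' the grid point selected by cross-validated weighted F1 and the feature
#' and class metadata needed for prediction.
#'
#' @slot engine one of "LR", "RF", "kNN", "SVM", "MLP".
#' @slot fit the underlying fitted object (for kNN, the training data).
#' @slot gridPoint named list, the selected hyper-parameters.
#' @slot cvScore cross-validated weighted F1 of the selected point.
#' @slot featureNames training feature columns, in order.
#' @slot classLevels stage levels the model predicts.
#' @export
setClass("MemorylessModel",
  representation(
    engine = "character",
    fit = "ANY",
    gridPoint = "list",
    cvScore = "numeric",
    featureNames = "character",
    classLevels = "character"
  )
)

#' LSTM classifier trained from first principles
#'
#' Gate weight matrices and biases of a single-layer LSTM with a dense
#' softmax readout, trained by backpropagation through time with Adam.
#' `params` holds `Wf, Wi, Wo, Wc` (hidden x features), `Uf, Ui, Uo, Uc`
#' (hidden x hidden), `bf, bi, bo, bc` (hidden), and the readout `V`
#' (classes x hidden), `by` (classes).
#'
#' @slot params named list of weight matrices/vectors.
#' @slot ns history steps the model was trained with.
#' @slot hiddenSize integer hidden width.
#' @slot candidateActivation "tanh" (standard) or "sigmoid" (as-printed variant).
#' @slot featureNames training feature columns.
#' @slot classLevels stage levels.
#' @slot lossHistory per-epoch mean training cross-entropy.
#' @slot scaler min-max scaler fitted on training features (list or NULL).
#' @export
setClass("LSTMModel",
  representation(
    params = "list",
    ns = "integer",
    hiddenSize = "integer",
    candidateActivation = "character",
    featureNames = "character",
    classLevels = "character",
    lossHistory = "numeric",
    scaler = "ANY"
  )
)

#' Weighted multiclass evaluation report
#'
#' The metric bundle used throughout: accuracy, support-weighted precision,
#' recall and F1, Cohen's kappa, the multiclass Matthews coefficient, an
#' optional RMSE on one-hot residuals, and the predicted-by-true confusion
#' matrix.
#'
#' @slot accuracy overall agreement rate.
#' @slot precisionW support-weighted precision.
#' @slot recallW support-weighted recall (identically equal to accuracy).
#' @slot f1W support-weighted F1.
#' @slot kappa Cohen's kappa (chance-corrected agreement).
#' @slot matthews multiclass Matthews correlation coefficient.
#' @slot rmse RMSE of class probabilities against one-hot truth (`NA` if no
#'   probabilities were supplied).
#' @slot confusion predicted x true count matrix.
#' @slot nTest number of scored rows.
#' @slot metadata free-form list (model, ns, seed, schema, ...).
#' @export
setClass("EvalReport",
  representation(
    accuracy = "numeric", precisionW = "numeric", recallW = "numeric",
    f1W = "numeric", kappa = "numeric", matthews = "numeric",
    rmse = "numeric", confusion = "matrix", nTest = "integer",
    metadata = "list"
  )
)

setValidity("EvalReport", function(object) {
  msgs <- character()
  rates <- c(object@accuracy, object@precisionW, object@recallW, object@f1W)
  if (any(rates < -1e-12 | rates > 1 + 1e-12))
    msgs <- c(msgs, "rates must lie in [0, 1]")
  if (object@kappa < -1 - 1e-12 || object@kappa > 1 + 1e-12)
    msgs <- c(msgs, "kappa must lie in [-1, 1]")
  if (sum(object@confusion) != object@nTest)
    msgs <- c(msgs, "confusion matrix total must equal nTest")
  if (length(msgs)) msgs else TRUE
})
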