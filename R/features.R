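## Engineered feature channels: cosine clock, activity-to-light inference,
## activity counts from raw acceleration, Gaussian / difference-of-Gaussians
## smoothing, heart-rate interpolation and variation, positivity and min-max
## transforms. Everything in this file is deterministic.

#' Cosine clock feature
#'
#' `C(t) = cos(2*pi*t / 24)` for `t` in hours since sleep onset: a cosine
#' that rises and falls overnight with one full period per 24 h.
#'
#' @param tHours numeric, hours since sleep onset.
#' @param periodHours clock period, hours (default 24).
#' @return numeric series in `[-1, 1]`.
#' @export
cosineClock <- function(tHours, periodHours = 24) {
  stopifnot(all(is.finite(tHours)))
  cos(2 * pi * tHours / periodHours)
}

#' Infer light intensity from activity counts
#'
#' Wearables rarely log illuminance; activity is taken as a proxy on the
#' grounds that activity happens under light. Epochs with counts above
#' `threshold` map to `activeLux`, the rest to `darkLux`.
#'
#' @param counts nonnegative activity counts (numeric vector or an
#'   [EpochTable-class] with a `counts`/`steps` column).
#' @param activeLux intensity assigned to active epochs (default 1000 lux).
#' @param darkLux intensity assigned to inactive epochs (default 0 lux).
#' @param threshold activity threshold (default 0: any activity = light).
#' @return numeric lux series.
#' @export
activityToLight <- function(counts, activeLux = 1000, darkLux = 0,
                            threshold = 0) {
  if (is(counts, "EpochTable")) {
    d <- epochData(counts)
    col <- intersect(c("counts", "steps"), names(d))[1]
    if (is.na(col)) stop("no counts/steps column in EpochTable")
    counts <- d[[col]]
  }
  if (any(counts < 0, na.rm = TRUE)) stop("activity counts must be >= 0")
  ifelse(counts > threshold, activeLux, darkLux)
}

#' Activity counts from raw triaxial acceleration
#'
#' The usual actigraphy reduction: high-pass filter each axis to remove the
#' gravity component, rectify, take the per-epoch maximum of the vector
#' magnitude, and scale to integer counts.
#'
#' @param accel `data.frame` with columns `x`, `y`, `z` in g.
#' @param fs sampling rate, Hz (>= 10).
#' @param epoch epoch length, seconds.
#' @param cutoffHz high-pass cutoff (default 0.25 Hz).
#' @param countScale counts per g (default 1000).
#' @return integer counts, one per complete epoch.
#' @export
accelerationToCounts <- function(accel, fs, epoch = 30, cutoffHz = 0.25,
                                 countScale = 1000) {
  stopifnot(fs >= 10)
  n <- nrow(accel)
  perEpoch <- as.integer(round(fs * epoch))
  if (n < perEpoch) stop("fewer samples than one epoch")
  ## one-pole high-pass per axis removes the gravity (DC) component
  hp <- vapply(c("x", "y", "z"), function(a)
    filtfiltHP(accel[[a]], cutoffHz, fs), numeric(n))
  mag <- sqrt(rowSums(hp^2))
  nEp <- n %/% perEpoch
  idx <- rep(seq_len(nEp), each = perEpoch)
  peak <- tapply(mag[seq_len(nEp * perEpoch)], idx, max)
  as.integer(round(as.numeric(peak) * countScale))
}

## simple one-pole high-pass: y[i] = a*(y[i-1] + x[i] - x[i-1])
filtfiltHP <- function(x, cutoffHz, fs) {
  rc <- 1 / (2 * pi * cutoffHz)
  a <- rc / (rc + 1 / fs)
  y <- numeric(length(x))
  for (i in seq_along(x)[-1]) y[i] <- a * (y[i - 1] + x[i] - x[i - 1])
  y
}

#' Gaussian / difference-of-Gaussians convolution
#'
#' The Gaussian kernel is unit-sum (constants pass unchanged); the DoG
#' kernel is the difference of two unit-sum Gaussians, hence zero-sum
#' (constants map to 0, changes are highlighted). Kernel support is
#' truncated at `truncation * max(sigma)` samples; edges use reflect
#' padding by default.
#'
#' @param series uniform numeric series.
#' @param sigma kernel width in samples (convert seconds with
#'   `sigma_seconds / interval`).
#' @param sigma2 second, wider Gaussian width in samples; supplying it
#'   selects the difference-of-Gaussians kernel (requires `sigma2 > sigma`).
#' @param truncation kernel half-width in multiples of the largest sigma.
#' @param padding `"reflect"`, `"nearest"` or `"zero"`.
#' @return filtered series, same length.
#' @export
convolveSeries <- function(series, sigma, sigma2 = NULL, truncation = 4,
                           padding = c("reflect", "nearest", "zero")) {
  padding <- match.arg(padding)
  stopifnot(sigma > 0)
  if (!is.null(sigma2) && sigma2 <= sigma)
    stop("difference-of-Gaussians requires sigma2 > sigma")
  smax <- max(sigma, sigma2)
  r <- as.integer(ceiling(truncation * smax))
  u <- (-r):r
  g1 <- exp(-u^2 / (2 * sigma^2)); g1 <- g1 / sum(g1)
  kernel <- if (is.null(sigma2)) g1 else {
    g2 <- exp(-u^2 / (2 * sigma2^2)); g2 <- g2 / sum(g2)
    g1 - g2
  }
  n <- length(series)
  if (n < 1L) stop("empty series")
  if (n <= r && padding == "reflect")
    stop("series shorter than the kernel half-width")
  padded <- switch(padding,
    reflect = c(series[(r + 1):2], series, series[(n - 1):(n - r)]),
    nearest = c(rep(series[1], r), series, rep(series[n], r)),
    zero    = c(rep(0, r), series, rep(0, r)))
  out <- stats::filter(padded, kernel, method = "convolution", sides = 2)
  as.numeric(out[(r + 1):(r + n)])
}

#' Interpolate heart rate to a 1 s grid and smooth
#'
#' Linear interpolation of the epoch-sampled heart rate onto a 1 s grid over
#' the recording span, followed by Gaussian smoothing (default sigma 120 s).
#' A single-sample input is extended as a constant, with a warning.
#'
#' @param hr an [EpochTable-class] with an `hr` column, or a `data.frame`
#'   with `time` and `hr`.
#' @param smoothSigmaSec Gaussian sigma in seconds; 0 disables smoothing.
#' @return `data.frame` with 1 s `time` grid and `hr`.
#' @export
hrPreprocess <- function(hr, smoothSigmaSec = 120) {
  df <- if (is(hr, "EpochTable")) as.data.frame(hr) else hr
  stopifnot(all(c("time", "hr") %in% names(df)))
  tt <- as.numeric(df$time)
  grid <- seq(tt[1], tt[length(tt)], by = 1)
  if (nrow(df) < 2L) {
    warning("single heart-rate sample: extending as a constant")
    out <- rep(df$hr[1], length(grid))
  } else {
    out <- approx(tt, df$hr, xout = grid)$y
  }
  if (smoothSigmaSec > 0 && length(out) > smoothSigmaSec)
    out <- convolveSeries(out, sigma = smoothSigmaSec)
  data.frame(time = as.POSIXct(grid, origin = "1970-01-01", tz = "UTC"),
             hr = out)
}

#' Heart-rate variation
#'
#' Absolute difference of consecutive heart-rate samples divided by the
#' mean heart rate over the sleep period:
#' `v_i = |hr_{i+1} - hr_i| / sleepPeriodMean`.
#'
#' @param hr numeric heart-rate series.
#' @param sleepPeriodMean mean heart rate over the sleep period, beats/min;
#'   defaults to `mean(hr)`.
#' @return numeric series of length `length(hr) - 1`.
#' @export
hrVariation <- function(hr, sleepPeriodMean = mean(hr)) {
  if (!is.finite(sleepPeriodMean) || sleepPeriodMean == 0)
    stop("sleep-period mean heart rate must be nonzero")
  abs(diff(hr)) / sleepPeriodMean
}

#' Shift a series positive and log-transform
#'
#' `log2(y + 1 - min(y))`: order-preserving, output minimum exactly 0.
#'
#' @param y finite numeric series.
#' @return transformed series, same length.
#' @export
logPositify <- function(y) {
  stopifnot(length(y) > 0, all(is.finite(y)))
  log2(y + 1 - min(y))
}

#' Min-max scaling fitted on training data
#'
#' Columnwise `(v - min) / (max - min)` with bounds fitted on `train` and
#' applied unchanged to `applyTo` (values outside the training range map
#' outside `[0, 1]`; no clipping). Constant training columns map to 0.
#'
#' @param train numeric `data.frame`/matrix to fit bounds on.
#' @param applyTo optional second table scaled with the same bounds.
#' @return list with `train`, `applied` (or `NULL`), and `scaler`
#'   (`mins`/`maxs` named vectors, reusable via [applyScaler()]).
#' @export
minMaxScale <- function(train, applyTo = NULL) {
  train <- as.data.frame(train)
  num <- vapply(train, is.numeric, logical(1))
  mins <- vapply(train[num], min, numeric(1), na.rm = TRUE)
  maxs <- vapply(train[num], max, numeric(1), na.rm = TRUE)
  scaler <- list(mins = mins, maxs = maxs)
  list(train = applyScaler(train, scaler),
       applied = if (!is.null(applyTo)) applyScaler(applyTo, scaler),
       scaler = scaler)
}

#' @rdname minMaxScale
#' @param x table to scale.
#' @param scaler a scaler from [minMaxScale()].
#' @export
applyScaler <- function(x, scaler) {
  x <- as.data.frame(x)
  for (cn in names(scaler$mins)) {
    if (!cn %in% names(x)) next
    rng <- scaler$maxs[[cn]] - scaler$mins[[cn]]
    x[[cn]] <- if (rng == 0) 0 else (x[[cn]] - scaler$mins[[cn]]) / rng
  }
  x
}

#' Invert a min-max scaler on scaled training columns
#' @rdname minMaxScale
#' @export
invertScaler <- function(x, scaler) {
  x <- as.data.frame(x)
  for (cn in names(scaler$mins)) {
    if (!cn %in% names(x)) next
    rng <- scaler$maxs[[cn]] - scaler$mins[[cn]]
    x[[cn]] <- if (rng == 0) scaler$mins[[cn]] else
      x[[cn]] * rng + scaler$mins[[cn]]
  }
  x
}
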