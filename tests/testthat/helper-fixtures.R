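# Shared fixtures: economical generator settings (60 s epochs, no raw
# acceleration channel) and an independent, definitional metric oracle.

fastGenConfig <- function(...) {
  generatorConfig(epochInterval = 60, accelFs = 0, ...)
}

featureSet <- c("timeH", "cosine", "circadian", "hr", "steps")

# Independent metric oracle: per-class loops straight from the definitions,
# deliberately not sharing code with scoreClassifier().
oracleMetrics <- function(yTrue, yPred) {
  lev <- sort(unique(c(yTrue, yPred)))
  n <- length(yTrue)
  acc <- sum(yTrue == yPred) / n
  prec <- rec <- f1 <- w <- numeric(length(lev))
  for (j in seq_along(lev)) {
    cls <- lev[j]
    tp <- sum(yTrue == cls & yPred == cls)
    fp <- sum(yTrue != cls & yPred == cls)
    fn <- sum(yTrue == cls & yPred != cls)
    prec[j] <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec[j] <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1[j] <- if (prec[j] + rec[j] > 0)
      2 * prec[j] * rec[j] / (prec[j] + rec[j]) else 0
    w[j] <- sum(yTrue == cls) / n
  }
  po <- acc
  pe <- 0
  for (j in seq_along(lev))
    pe <- pe + (sum(yPred == lev[j]) / n) * (sum(yTrue == lev[j]) / n)
  kappa <- if (pe < 1) (po - pe) / (1 - pe) else 0
  list(acc = acc, precW = sum(w * prec), recW = sum(w * rec),
       f1W = sum(w * f1), kappa = kappa)
}

randomLabels <- function(n, k, seed) {
  set.seed(seed)
  lev <- paste0("s", seq_len(k))
  list(truth = sample(lev, n, replace = TRUE, prob = runif(k) + 0.2),
       pred = sample(lev, n, replace = TRUE, prob = runif(k) + 0.2))
}

# tiny labeled feature frame on a uniform grid, for windowing tests
toyFeatureFrame <- function(n, interval = 60, seed = 1) {
  set.seed(seed)
  data.frame(
    time = as.POSIXct("2022-01-01 22:00:00", tz = "UTC") +
      (seq_len(n) - 1) * interval,
    f1 = rnorm(n), f2 = rnorm(n), f3 = rnorm(n),
    stage = sample(c("wake", "light", "deep", "REM"), n, replace = TRUE)
  )
}
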