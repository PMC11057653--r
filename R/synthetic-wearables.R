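## Synthetic wearable nights: a dwell-time-constrained semi-Markov cycle model
## for the hypnogram, stage-conditional emission for heart rate / steps /
## acceleration, and run-length-encoded summary records with deliberate
## overlapping short/long duplicates.

FINE_STAGES <- c("wake", "N1", "N2", "N3", "REM", "unscored")

#' Stage label sets
#'
#' The shipped label sets: `FOUR` = wake/light/deep/REM (N1 and N2 collapse
#' to light, N3 to deep) and `SIX` = the fine wake/N1/N2/N3/REM/unscored
#' labels. The mapping is total over the fine stages; in `FOUR`, unscored
#' epochs map to wake (movement-artifact convention).
#'
#' @param name `"FOUR"` or `"SIX"`.
#' @return list with `name`, `labels` (ordered coarse labels) and `mapping`
#'   (named character from fine stage to coarse label).
#' @export
stageLabelSet <- function(name = c("FOUR", "SIX")) {
  name <- match.arg(name)
  if (name == "FOUR") {
    mapping <- c(wake = "wake", N1 = "light", N2 = "light", N3 = "deep",
                 REM = "REM", unscored = "wake")
    labels <- c("wake", "light", "deep", "REM")
  } else {
    mapping <- setNames(FINE_STAGES, FINE_STAGES)
    labels <- FINE_STAGES
  }
  stopifnot(!anyDuplicated(labels), all(FINE_STAGES %in% names(mapping)))
  list(name = name, labels = labels, mapping = mapping)
}

#' Default generator configuration
#'
#' Defaults encode the assumed sleep architecture: 4-6 cycles averaging
#' 90 min with the first cycle shortest; dwell ranges N1 1-5, N2 10-60,
#' N3 20-40, REM 10-60 min; long-run stage proportions wake 12.2%,
#' light 50.1%, deep 18.1%, REM 19.6%; overlapping nocturnal heart-rate
#' emission (wake > REM > light > deep); steps only in wake epochs.
#'
#' @param nightLength minutes; used by the memoryless variant and as a
#'   feasibility bound (cycle-model nights have emergent length
#'   `~ nCycles * cycleLengthMean`).
#' @param epochInterval seconds, one of 15/30/60.
#' @param nCyclesRange inclusive integer range of cycles per night.
#' @param cycleLengthMean mean cycle length, minutes.
#' @param dwellRanges named list of minute pairs for N1, N2, N3, REM.
#' @param targetProportions named fractions for wake/light/deep/REM, sum 1.
#' @param hrEmission named list of `c(mean, sd)` beats/min per coarse stage.
#' @param stepEmission named per-stage probability of a nonzero-step epoch.
#' @param accelNoiseSd base accelerometer noise sd, g.
#' @param accelFs accelerometer sampling rate, Hz (0 disables the channel).
#' @param historyDependence semi-Markov cycle model (`TRUE`) or memoryless
#'   first-order chain with the same stationary proportions (`FALSE`).
#' @return a validated [GeneratorConfig-class].
#' @export
generatorConfig <- function(nightLength = 450,
                            epochInterval = 30,
                            nCyclesRange = c(4L, 6L),
                            cycleLengthMean = 90,
                            dwellRanges = list(N1 = c(1, 5), N2 = c(10, 60),
                                               N3 = c(20, 40), REM = c(10, 60)),
                            targetProportions = c(wake = 0.122, light = 0.501,
                                                  deep = 0.181, REM = 0.196),
                            hrEmission = list(wake = c(72, 8), REM = c(66, 6),
                                              light = c(62, 5), deep = c(56, 4)),
                            stepEmission = c(wake = 0.3, light = 0, deep = 0,
                                             REM = 0),
                            accelNoiseSd = 0.02,
                            accelFs = 10,
                            historyDependence = TRUE) {
  new("GeneratorConfig",
      nightLength = nightLength, epochInterval = epochInterval,
      nCyclesRange = as.integer(nCyclesRange), cycleLengthMean = cycleLengthMean,
      dwellRanges = dwellRanges, targetProportions = targetProportions,
      hrEmission = hrEmission, stepEmission = stepEmission,
      accelNoiseSd = accelNoiseSd, accelFs = accelFs,
      historyDependence = historyDependence)
}

## Uniform-draw interval with a prescribed mean, inside a hard dwell range.
## [target - h, target + h] subset of [lo, hi] with h capped at rel * target,
## so the draw's mean is exactly the target (clamped to the near bound when
## the target falls outside the range).
drawInterval <- function(target, range, rel = 0.3) {
  lo <- range[1]; hi <- range[2]
  if (target <= lo) return(c(lo, lo))
  if (target >= hi) return(c(hi, hi))
  h <- min(rel * target, target - lo, hi - target)
  c(target - h, target + h)
}

runif1 <- function(ab) if (ab[1] == ab[2]) ab[1] else runif(1, ab[1], ab[2])

## minutes -> epoch count, clamped so ranged dwells stay inside their range
epochsFor <- function(minutes, intervalSec, range = NULL) {
  n <- max(1L, as.integer(round(minutes * 60 / intervalSec)))
  if (!is.null(range)) {
    n <- max(n, as.integer(ceiling(range[1] * 60 / intervalSec)))
    n <- min(n, as.integer(floor(range[2] * 60 / intervalSec)))
  }
  n
}

#' Generate a single-night hypnogram
#'
#' With `historyDependence = TRUE` (default), builds the night as
#' `nCycles` concatenated sleep cycles, each traversing
#' wake -> N1 -> N2 -> (N3) -> REM with dwell times drawn inside the
#' configured ranges. Per-cycle stage budgets are derived in closed form from
#' `targetProportions * cycleLengthMean`, so pooled epoch fractions converge
#' to the targets; deep sleep, whose 20-40 min dwell floor exceeds its
#' per-cycle budget, is present in a stochastically rounded fraction of
#' cycles, concentrated in the earliest ones. The first cycle's budgets are
#' shrunk by 0.8, making it the shortest.
#'
#' With `historyDependence = FALSE`, emits a memoryless first-order chain:
#' each epoch resamples the stage from `targetProportions` with a fixed
#' hazard (geometric dwell, mean 20 min), the negative control in which past
#' context carries no extra information.
#'
#' @param config a [GeneratorConfig-class].
#' @param seed integer seed; identical `(config, seed)` give identical nights.
#' @param start night start time (`POSIXct`).
#' @param labelSet a [stageLabelSet()] (default `FOUR`).
#' @return an [EpochTable-class] with columns `stage` (mapped labels),
#'   `fineStage`, and `cycle`.
#' @export
generateHypnogram <- function(config, seed = 1L,
                              start = as.POSIXct("2021-12-16 22:00:00",
                                                 tz = "UTC"),
                              labelSet = stageLabelSet("FOUR")) {
  stopifnot(is(config, "GeneratorConfig"))
  validObject(config)
  ep <- config@epochInterval
  minCycle <- sum(vapply(config@dwellRanges[c("N1", "N2", "REM")],
                         `[`, numeric(1), 1L))
  if (config@nightLength < config@nCyclesRange[1] * minCycle)
    stop("nightLength too short for the minimum cycle count (need >= ",
         config@nCyclesRange[1] * minCycle, " min)")
  set.seed(seed)

  if (!config@historyDependence) {
    nEp <- as.integer(round(config@nightLength * 60 / ep))
    tp <- config@targetProportions
    hazard <- ep / (20 * 60)            # geometric dwell, mean 20 min
    coarse <- character(nEp)
    coarse[1] <- sample(names(tp), 1L, prob = tp)
    jump <- runif(nEp) < hazard
    for (i in seq_len(nEp)[-1])
      coarse[i] <- if (jump[i]) sample(names(tp), 1L, prob = tp) else coarse[i - 1]
    fine <- c(wake = "wake", light = "N2", deep = "N3", REM = "REM")[coarse]
    df <- data.frame(fineStage = unname(fine), cycle = 1L)
  } else {
    n <- if (config@nCyclesRange[1] == config@nCyclesRange[2])
      config@nCyclesRange[1] else
      sample(config@nCyclesRange[1]:config@nCyclesRange[2], 1L)
    tp <- config@targetProportions
    L <- config@cycleLengthMean
    dr <- config@dwellRanges
    m1 <- mean(dr$N1)
    m3 <- mean(dr$N3)
    ## per-cycle stage budgets (minutes in a nominal 90-min cycle)
    cWake <- unname(tp["wake"]) * L
    cN2 <- unname(tp["light"]) * L - m1
    cDeep <- unname(tp["deep"]) * L
    cREM <- unname(tp["REM"]) * L
    sFirst <- 0.8                        # first cycle shortest
    ## Deep bouts cannot be shorter than their 20-40 min dwell floor, so deep
    ## is present only in the first kDeep cycles (deep sleep concentrates
    ## early); kDeep is stochastically rounded so that expected deep time is
    ## exactly the target. Cycles without deep redistribute its budget to
    ## the other stages, keeping every cycle near the nominal length.
    denom <- L - cDeep
    qn <- if (cDeep > 0) cDeep * (n - 1 + sFirst) / m3 + (1 - sFirst) else 0
    qn <- min(n, max(0, qn))
    kDeep <- as.integer(floor(qn)) + rbinom(1L, 1L, qn - floor(qn))
    kDeep <- min(max(kDeep, 0L), n)
    fine <- character(0)
    cyc <- integer(0)
    for (j in seq_len(n)) {
      s <- if (j == 1L) sFirst else 1
      deepAlloc <- if (j <= kDeep) s * m3 else 0
      phi <- (s * L - deepAlloc) / denom
      wakeMin <- runif1(c(0.7, 1.3) * phi * cWake)
      n1Min <- runif1(drawInterval(phi * m1, dr$N1))
      n2Min <- runif1(drawInterval(phi * cN2, dr$N2))
      remMin <- runif1(drawInterval(phi * cREM, dr$REM))
      bouts <- list(c("wake", wakeMin), c("N1", n1Min), c("N2", n2Min))
      if (deepAlloc > 0) {
        n3Min <- runif1(drawInterval(deepAlloc, dr$N3))
        bouts <- c(bouts, list(c("N3", n3Min)))
      }
      bouts <- c(bouts, list(c("REM", remMin)))
      for (b in bouts) {
        rng <- switch(b[1], N1 = dr$N1, N2 = dr$N2, N3 = dr$N3, REM = dr$REM,
                      NULL)
        nb <- if (b[1] == "wake" && as.numeric(b[2]) * 60 / ep < 0.5) 0L
              else epochsFor(as.numeric(b[2]), ep, rng)
        if (nb > 0L) {
          fine <- c(fine, rep(b[1], nb))
          cyc <- c(cyc, rep(j, nb))
        }
      }
    }
    df <- data.frame(fineStage = fine, cycle = cyc)
  }

  badFine <- setdiff(unique(df$fineStage), names(labelSet$mapping))
  if (length(badFine)) stop("unmapped fine stages: ", paste(badFine, collapse = ", "))
  df$stage <- unname(labelSet$mapping[df$fineStage])
  df <- df[c("stage", "fineStage", "cycle")]
  EpochTable(start + (seq_len(nrow(df)) - 1L) * ep, ep, df)
}

#' Generate stage-conditional sensor signals for a hypnogram
#'
#' Heart rate is drawn per epoch from the stage's Gaussian emission
#' (defaults ordered wake > REM > light > deep); steps are zero in all sleep
#' stages and sparse bursts in wake epochs; triaxial acceleration is
#' stage-modulated noise around gravity at `accelFs` Hz.
#'
#' @param hypnogram an [EpochTable-class] with a `stage` column.
#' @param config a [GeneratorConfig-class].
#' @param seed integer seed.
#' @return list with elements `hypnogram`, `signals` (an [EpochTable-class]
#'   with `hr` and `steps`), and `acceleration` (a `data.frame`
#'   time/x/y/z, or `NULL` when `accelFs == 0`).
#' @export
generateSignals <- function(hypnogram, config, seed = 1L) {
  stopifnot(is(hypnogram, "EpochTable"), is(config, "GeneratorConfig"))
  set.seed(seed + 1000003L)
  st <- as.character(stages(hypnogram))
  unknown <- setdiff(unique(st), names(config@hrEmission))
  if (length(unknown))
    stop("unknown stage label(s): ", paste(unknown, collapse = ", "))
  n <- nEpochs(hypnogram)
  em <- config@hrEmission
  mu <- vapply(st, function(s) em[[s]][1], numeric(1))
  sdv <- vapply(st, function(s) em[[s]][2], numeric(1))
  hr <- rnorm(n, mu, sdv)
  rate <- config@stepEmission[st]
  rate[is.na(rate)] <- 0
  steps <- ifelse(rbinom(n, 1L, rate) == 1L, rpois(n, 12) + 1L, 0L)
  signals <- EpochTable(epochTimestamps(hypnogram), epochInterval(hypnogram),
                        data.frame(hr = hr, steps = steps))
  accel <- NULL
  if (config@accelFs > 0) {
    fs <- config@accelFs
    perEpoch <- as.integer(round(fs * epochInterval(hypnogram)))
    factor <- c(wake = 3, REM = 1.5, light = 1, deep = 0.7)[st]
    factor[is.na(factor)] <- 1
    sdA <- rep(config@accelNoiseSd * factor, each = perEpoch)
    nS <- n * perEpoch
    t0 <- as.numeric(epochTimestamps(hypnogram)[1])
    accel <- data.frame(
      time = as.POSIXct(t0 + (seq_len(nS) - 1) / fs,
                        origin = "1970-01-01", tz = "UTC"),
      x = rnorm(nS, 0, sdA), y = rnorm(nS, 0, sdA), z = 1 + rnorm(nS, 0, sdA))
  }
  list(hypnogram = hypnogram, signals = signals, acceleration = accel)
}

#' Run-length encode a hypnogram into summary sleep records, with duplicates
#'
#' Encodes the hypnogram's maximal stage runs as `Long` records, then injects
#' overlapping `Short` records at `duplicateRate` of the epochs: each chosen
#' epoch keeps the true stage in a Short record (30 s, or 60 s spanning two
#' 30 s epochs when the stage is locally constant) while the Long coverage at
#' that epoch is corrupted to a different stage. Short-wins merging therefore
#' recovers the hypnogram exactly, and the Long records always partition the
#' night.
#'
#' @param hypnogram an [EpochTable-class] with a `stage` column.
#' @param duplicateRate fraction of epochs to overlap, in `[0, 1]`.
#' @param seed integer seed.
#' @return `data.frame` with columns `start` (POSIXct), `duration_s`,
#'   `interval_s`, `stage`, `type` (`Long`/`Short`), sorted by time.
#' @export
emitSleepRecords <- function(hypnogram, duplicateRate = 0, seed = 1L) {
  stopifnot(is(hypnogram, "EpochTable"))
  if (duplicateRate < 0 || duplicateRate > 1)
    stop("duplicateRate must be in [0, 1]")
  set.seed(seed + 2000003L)
  ep <- epochInterval(hypnogram)
  ts <- epochTimestamps(hypnogram)
  truth <- as.character(stages(hypnogram))
  n <- length(truth)
  labels <- unique(truth)

  nDup <- as.integer(round(duplicateRate * n))
  chosen <- if (nDup > 0) sort(sample.int(n, nDup)) else integer(0)

  longStage <- truth
  shorts <- list()
  covered <- logical(n)
  for (i in chosen) {
    if (covered[i]) next
    span <- 1L
    if (ep == 30 && i < n && truth[i + 1L] == truth[i] && !covered[i + 1L] &&
        runif(1) < 0.5)
      span <- 2L                       # one 60 s Short over two 30 s epochs
    idx <- i:(i + span - 1L)
    covered[idx] <- TRUE
    for (k in idx) {
      alt <- setdiff(c("wake", "light", "deep", "REM", labels), truth[k])
      longStage[k] <- sample(alt, 1L)
    }
    shorts[[length(shorts) + 1L]] <- data.frame(
      start = ts[i], duration_s = span * ep, interval_s = span * ep,
      stage = truth[i], type = "Short")
  }

  r <- rle(longStage)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  longs <- data.frame(start = ts[starts], duration_s = r$lengths * ep,
                      interval_s = ep, stage = r$values, type = "Long")
  out <- rbind(longs, if (length(shorts)) do.call(rbind, shorts))
  out <- out[order(out$start, out$type), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Generate a batch of synthetic nights
#'
#' @param config a [GeneratorConfig-class].
#' @param nights number of nights.
#' @param seed integer; night `i` uses `seed + i`.
#' @param signals also emit heart rate / steps (and acceleration if enabled)?
#' @param duplicateRate duplicate-record rate passed to [emitSleepRecords()].
#' @return list of nights; each has `hypnogram`, and when requested
#'   `signals`, `acceleration`, `records`.
#' @export
generateNights <- function(config, nights, seed = 1L, signals = FALSE,
                           duplicateRate = 0) {
  lapply(seq_len(nights), function(i) {
    s <- seed + i
    start <- as.POSIXct("2021-12-01 22:00:00", tz = "UTC") + (i - 1) * 86400
    hyp <- generateHypnogram(config, seed = s, start = start)
    night <- list(hypnogram = hyp)
    if (signals) {
      sig <- generateSignals(hyp, config, seed = s)
      night$signals <- sig$signals
      night$acceleration <- sig$acceleration
    }
    if (duplicateRate > 0 || signals)
      night$records <- emitSleepRecords(hyp, duplicateRate, seed = s)
    night
  })
}

#' Six-row example of overlapping short/long device records
#'
#' A small fixture of summarized stage records in which a 60 s Short record
#' and a 30 s Short record overlap Long coverage, the shape produced by
#' devices that store both granularities. Short-wins merging yields four
#' epochs: light, light, wake, wake.
#'
#' @return `data.frame` in the [emitSleepRecords()] record format.
#' @export
exampleOverlapRecords <- function() {
  ts <- function(s) as.POSIXct(s, tz = "UTC")
  data.frame(
    start = ts(c("2021-12-16 06:37:00", "2021-12-16 06:37:30",
                 "2021-12-16 06:38:00", "2021-12-16 06:38:00",
                 "2021-12-16 06:38:30", "2021-12-16 06:38:30")),
    duration_s = c(30, 30, 60, 30, 30, 30),
    interval_s = c(30, 30, 60, 30, 30, 30),
    stage = c("light", "light", "wake", "light", "light", "wake"),
    type = c("Long", "Long", "Short", "Long", "Long", "Short")
  )
}

#' Write / read sleep records as delimited text
#'
#' @param records record `data.frame` as produced by [emitSleepRecords()].
#' @param path file path.
#' @export
writeSleepRecords <- function(records, path) {
  out <- records
  out$start <- format(out$start, "%Y-%m-%dT%H:%M:%S")
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeSleepRecords
#' @export
readSleepRecords <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  df$start <- as.POSIXct(df$start, format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  df
}
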