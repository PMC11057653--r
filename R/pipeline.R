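## End-to-end glue: synthetic nights -> labeled feature table with the
## engineered channels (cosine clock, circadian drive, heart rate, steps,
## time since onset), the input to windowing and the model studies.

#' Build the feature table for one night
#'
#' Computes the standard channel set from a night's hypnogram and signals:
#' `hr`, `steps`, `timeH` (hours since sleep onset), `cosine`
#' ([cosineClock()]), and `circadian` (the `x` coordinate of
#' [integrateCircadian()] driven by light inferred from steps).
#'
#' @param night a list with `hypnogram` and `signals` (see
#'   [generateNights()] with `signals = TRUE`).
#' @param patientId identifier stored in the `patientId` column.
#' @param oscillator a [CircadianParams-class].
#' @param circadianInit initial oscillator state (default
#'   `c(x = -1, xc = 0, n = 0)`: circadian low at night onset).
#' @return `data.frame` with `time`, `patientId`, features and `stage`.
#' @export
nightFeatureTable <- function(night, patientId = 1L,
                              oscillator = circadianParams(),
                              circadianInit = c(x = -1, xc = 0, n = 0)) {
  hyp <- night$hypnogram
  sig <- night$signals
  stopifnot(is(hyp, "EpochTable"), is(sig, "EpochTable"))
  ep <- epochInterval(hyp)
  tH <- (as.numeric(epochTimestamps(hyp)) -
           as.numeric(epochTimestamps(hyp)[1])) / 3600
  lux <- activityToLight(epochData(sig)$steps)
  circ <- integrateCircadian(lux, oscillator, init = circadianInit,
                             dt = ep)
  data.frame(
    time = epochTimestamps(hyp),
    patientId = patientId,
    timeH = tH,
    cosine = cosineClock(tH),
    circadian = circ$x[seq_along(tH)],
    hr = epochData(sig)$hr,
    steps = epochData(sig)$steps,
    stage = as.character(stages(hyp))
  )
}

#' Assemble a multi-night labeled feature table
#'
#' @param nights list from [generateNights()] (`signals = TRUE`).
#' @param ... passed to [nightFeatureTable()].
#' @return row-bound feature `data.frame`; nights are distinct patients so
#'   windows never cross a night boundary.
#' @export
assembleNights <- function(nights, ...) {
  do.call(rbind, lapply(seq_along(nights), function(i)
    nightFeatureTable(nights[[i]], patientId = i, ...)))
}
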