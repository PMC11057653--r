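## Sliding-window sequence construction: each labeled row is re-emitted with
## its ns predecessors as context, the input shape of the memory models.

#' @export
setMethod("stages", "WindowedDataset", function(x) x@labels)

#' @export
setMethod("memorySteps", "WindowedDataset", function(x) x@ns)

#' @export
setMethod("featureNames", "WindowedDataset", function(x) x@featureNames)

setMethod("show", "WindowedDataset", function(object) {
  d <- dim(object@sequences)
  cat(sprintf("WindowedDataset: %d sequences of %d step(s) x %d feature(s) (ns = %d)\n",
              d[1], d[2], d[3], object@ns))
  print(table(object@labels))
})

#' Build sliding-window sequences from a feature table
#'
#' Emits one sequence per index `i in [ns+1, N]` holding rows
#' `i-ns ... i` with the stage of row `i` as the label (`ns = 0` degenerates
#' to the memoryless row set). Windows never span a timestamp gap or a
#' patient boundary: the table is first split into contiguous
#' single-patient segments and each segment contributes `max(0, N - ns)`
#' sequences.
#'
#' @param table an [EpochTable-class] or `data.frame` with `time`, a
#'   `stage` column, optionally `patientId`, and numeric feature columns.
#' @param ns integer history steps, `0 <= ns < N`.
#' @param featureCols feature columns to use; defaults to every numeric
#'   column except `time`/`stage`/`patientId`/`cycle`.
#' @param interval grid interval, seconds (taken from the `EpochTable` when
#'   available; required for gap detection on plain frames).
#' @return a [WindowedDataset-class].
#' @export
makeWindows <- function(table, ns, featureCols = NULL, interval = NULL) {
  df <- if (is(table, "EpochTable")) as.data.frame(table) else table
  if (is(table, "EpochTable") && is.null(interval))
    interval <- epochInterval(table)
  if (is.null(interval)) {
    d <- diff(sort(as.numeric(df$time)))
    d <- d[d > 0]
    if (!length(d)) stop("interval required for gap detection")
    interval <- min(d)          # the grid spacing; larger diffs are gaps
  }
  stopifnot("stage" %in% names(df), "time" %in% names(df))
  ns <- as.integer(ns)
  if (ns < 0L) stop("ns must be >= 0")
  if (ns >= nrow(df)) stop("ns must be smaller than the table size")
  if (is.null(featureCols)) {
    num <- names(df)[vapply(df, is.numeric, logical(1))]
    featureCols <- setdiff(num, c("time", "patientId", "cycle"))
  }
  segs <- if ("patientId" %in% names(df))
    unlist(lapply(split(df, df$patientId), splitAtGaps, interval = interval),
           recursive = FALSE)
  else splitAtGaps(df, interval)

  seqList <- list(); labList <- list()
  for (seg in segs) {
    N <- nrow(seg)
    if (N <= ns) next
    X <- as.matrix(seg[, featureCols, drop = FALSE])
    for (i in (ns + 1L):N) {
      seqList[[length(seqList) + 1L]] <- X[(i - ns):i, , drop = FALSE]
      labList[[length(labList) + 1L]] <- seg$stage[i]
    }
  }
  if (!length(seqList)) stop("no window fits: every segment shorter than ns + 1")
  arr <- array(NA_real_, dim = c(length(seqList), ns + 1L, length(featureCols)),
               dimnames = list(NULL, NULL, featureCols))
  for (k in seq_along(seqList)) arr[k, , ] <- seqList[[k]]
  new("WindowedDataset", ns = ns, sequences = arr,
      labels = factor(unlist(labList)), featureNames = featureCols)
}

#' Flatten windowed sequences into a 2-D design matrix
#'
#' Row-major concatenation of each sequence into one vector of length
#' `(ns+1) * F`; columns are named `<feature>_lag<k>` with `lag0` the
#' current row. With `ns = 0` this is the original feature matrix.
#'
#' @param ds a [WindowedDataset-class].
#' @return list with `x` (matrix) and `y` (factor labels).
#' @export
flattenWindows <- function(ds) {
  stopifnot(is(ds, "WindowedDataset"))
  d <- dim(ds@sequences)
  steps <- d[2]; F <- d[3]
  x <- matrix(NA_real_, nrow = d[1], ncol = steps * F)
  cn <- character(steps * F)
  for (s in seq_len(steps)) {
    lag <- steps - s
    cols <- (s - 1L) * F + seq_len(F)
    x[, cols] <- ds@sequences[, s, , drop = TRUE]
    cn[cols] <- paste0(ds@featureNames, "_lag", lag)
  }
  colnames(x) <- cn
  list(x = x, y = ds@labels)
}

#' Rebuild a windowed dataset from its flattened form
#'
#' Inverse of [flattenWindows()] given the original `ns` and feature names.
#'
#' @param flat list from [flattenWindows()].
#' @param ns history steps.
#' @param featureNames feature names (length `F`).
#' @return a [WindowedDataset-class].
#' @export
unflattenWindows <- function(flat, ns, featureNames) {
  steps <- ns + 1L; F <- length(featureNames)
  stopifnot(ncol(flat$x) == steps * F)
  arr <- array(NA_real_, dim = c(nrow(flat$x), steps, F),
               dimnames = list(NULL, NULL, featureNames))
  for (s in seq_len(steps))
    arr[, s, ] <- flat$x[, (s - 1L) * F + seq_len(F), drop = FALSE]
  new("WindowedDataset", ns = as.integer(ns), sequences = arr,
      labels = flat$y, featureNames = featureNames)
}

#' Write a windowed dataset as delimited text plus a JSON sidecar
#'
#' @param ds a [WindowedDataset-class].
#' @param path CSV path; the sidecar is written to `<path>.json`.
#' @export
writeWindows <- function(ds, path) {
  flat <- flattenWindows(ds)
  df <- as.data.frame(flat$x)
  df$stage <- as.character(flat$y)
  write.csv(df, path, row.names = FALSE)
  meta <- sprintf(
    '{"ns": %d, "F": %d, "featureNames": [%s]}',
    ds@ns, length(ds@featureNames),
    paste(sprintf('"%s"', ds@featureNames), collapse = ", "))
  writeLines(meta, paste0(path, ".json"))
  invisible(path)
}
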