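#' @rdname EpochTable-class
#' @export
setMethod("nEpochs", "EpochTable", function(x) length(x@timestamps))

#' @rdname EpochTable-class
#' @export
setMethod("epochInterval", "EpochTable", function(x) x@interval)

#' @rdname EpochTable-class
#' @export
setMethod("epochTimestamps", "EpochTable", function(x) x@timestamps)

#' @rdname EpochTable-class
#' @export
setMethod("epochData", "EpochTable", function(x) x@data)

#' @rdname EpochTable-class
#' @export
setMethod("schemaId", "EpochTable", function(x) x@schemaId)

#' @export
setMethod("stages", "EpochTable", function(x) {
  if (!"stage" %in% names(x@data))
    stop("EpochTable has no 'stage' column")
  x@data$stage
})

setMethod("show", "EpochTable", function(object) {
  cat(sprintf("EpochTable: %d epochs @ %g s", nEpochs(object), object@interval))
  if (!is.na(object@schemaId)) cat(sprintf(" [schema %s]", object@schemaId))
  cat("\n")
  if (nEpochs(object)) {
    cat(sprintf("  span: %s .. %s\n",
                format(object@timestamps[1], "%Y-%m-%d %H:%M:%S"),
                format(tail(object@timestamps, 1), "%Y-%m-%d %H:%M:%S")))
  }
  cat(sprintf("  columns: %s\n", paste(names(object@data), collapse = ", ")))
})

#' Convert an EpochTable to a plain data.frame
#'
#' @param x an [EpochTable-class].
#' @param ... ignored.
#' @return `data.frame` with a leading `time` column.
#' @export
as.data.frame.EpochTable <- function(x, ...) {
  cbind(data.frame(time = x@timestamps), x@data)
}

## Build an EpochTable from a possibly non-uniform data.frame; used by the
## readers and the join. Uniformity is validated by the class.
epochTableFromFrame <- function(df, interval, schemaId = NA_character_) {
  stopifnot("time" %in% names(df))
  df <- df[order(df$time), , drop = FALSE]
  EpochTable(df$time, interval, df[setdiff(names(df), "time")], schemaId)
}

#' Split an EpochTable at timestamp gaps
#'
#' Returns maximal gap-free segments (consecutive rows exactly one interval
#' apart), the unit over which sliding windows are allowed to run.
#'
#' @param df data.frame with a `time` column, sorted.
#' @param interval grid interval, seconds.
#' @return list of data.frames, each gap-free.
#' @keywords internal
splitAtGaps <- function(df, interval) {
  if (nrow(df) <= 1L) return(list(df))
  d <- diff(as.numeric(df$time))
  brk <- which(abs(d - interval) > 1e-6)
  idx <- cbind(c(1L, brk + 1L), c(brk, nrow(df)))
  lapply(seq_len(nrow(idx)), function(i) df[idx[i, 1]:idx[i, 2], , drop = FALSE])
}

#' Write / read a delimited night table
#'
#' Plain CSV with an ISO-8601 `time` column; the epoch interval is stored in
#' a `# interval=<s>` header comment so a round trip restores the grid.
#'
#' @param x an [EpochTable-class].
#' @param path file path.
#' @return `readEpochTable` returns an [EpochTable-class].
#' @export
writeEpochTable <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# interval=%g", x@interval), con)
  if (!is.na(x@schemaId)) writeLines(sprintf("# schema=%s", x@schemaId), con)
  df <- as.data.frame(x)
  df$time <- format(df$time, "%Y-%m-%dT%H:%M:%S")
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname writeEpochTable
#' @export
readEpochTable <- function(path) {
  hdr <- readLines(path, n = 5L)
  hdr <- hdr[startsWith(hdr, "#")]
  getv <- function(key) {
    m <- grep(sprintf("^# %s=", key), hdr, value = TRUE)
    if (length(m)) sub(sprintf("^# %s=", key), "", m[1]) else NA_character_
  }
  interval <- as.numeric(getv("interval"))
  if (is.na(interval)) stop("missing '# interval=' header in ", path)
  df <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  df$time <- as.POSIXct(df$time, format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  epochTableFromFrame(df, interval, getv("schema"))
}
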