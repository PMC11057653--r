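## Preprocessing of summarized interval records: expansion onto an epoch
## grid, short-wins de-duplication, timestamp floor alignment, natural joins
## and the named instance schemas.

#' Expand a summarized sleep record onto an epoch grid
#'
#' A record covering `duration_s` seconds from `start` becomes
#' `duration_s / targetInterval` consecutive entries, all carrying the
#' record's stage (e.g. a 1,200 s deep-sleep record at 30 s epochs becomes
#' 40 entries). Durations that are not a multiple of the target interval are
#' truncated to the last full epoch, with a message.
#'
#' @param record one-row `data.frame` with `start`, `duration_s`,
#'   `interval_s`, `stage`, `type` (see [emitSleepRecords()]).
#' @param targetInterval target epoch length, seconds (15, 30 or 60).
#' @return `data.frame` with columns `time`, `stage`, `interval_s`, `type`,
#'   one row per target epoch.
#' @export
expandRecord <- function(record, targetInterval = 30) {
  stopifnot(targetInterval %in% c(15, 30, 60))
  dur <- record$duration_s[1]
  if (dur <= 0) stop("record duration must be positive")
  nEntries <- dur %/% targetInterval
  if (nEntries < 1L)
    stop("record shorter than one target epoch (", dur, " s < ",
         targetInterval, " s)")
  if (dur %% targetInterval != 0)
    message("truncating ", dur %% targetInterval,
            " s remainder of a record to the last full epoch")
  data.frame(
    time = record$start[1] + (seq_len(nEntries) - 1L) * targetInterval,
    stage = record$stage[1],
    interval_s = targetInterval,
    type = record$type[1]
  )
}

#' Expand a whole record table
#'
#' @param records record `data.frame` (several rows).
#' @param targetInterval epoch length, seconds.
#' @return row-bound expansion of every record, sorted by time.
#' @export
expandRecords <- function(records, targetInterval = 30) {
  out <- do.call(rbind, lapply(seq_len(nrow(records)), function(i)
    expandRecord(records[i, , drop = FALSE], targetInterval)))
  out[order(out$time), , drop = FALSE]
}

#' Merge expanded entries, short records winning over long
#'
#' Where a timestamp carries both Long and Short coverage, the Short stage is
#' kept (the device's finer-granularity record is taken as the truth);
#' otherwise the unique entry is kept. Identical duplicate Short entries are
#' collapsed; two conflicting Short stages at one timestamp are an error.
#'
#' @param entries expanded entries from [expandRecords()] (single interval).
#' @return an [EpochTable-class] with a `stage` column, one row per
#'   timestamp, sorted; non-contiguous timestamps are not required here (the
#'   result grid is re-validated only if gap-free).
#' @export
mergeShortLong <- function(entries) {
  stopifnot(all(c("time", "stage", "type") %in% names(entries)))
  iv <- unique(entries$interval_s)
  if (length(iv) != 1L)
    stop("expand records to a single interval before merging")
  split_ <- split(entries, as.numeric(entries$time))
  rows <- lapply(split_, function(g) {
    sh <- g[g$type == "Short", , drop = FALSE]
    if (nrow(sh)) {
      if (length(unique(sh$stage)) > 1L)
        stop("conflicting Short stages at ", format(g$time[1]))
      g <- sh[1L, , drop = FALSE]
    } else {
      g <- g[1L, , drop = FALSE]
    }
    g[c("time", "stage")]
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$time), , drop = FALSE]
  rownames(out) <- NULL
  d <- diff(as.numeric(out$time))
  if (length(d) && any(abs(d - iv) > 1e-6)) {
    ## merged sequence has gaps; return the densest contiguous representation
    ## as a plain frame wrapped lazily: callers join on time anyway
    return(structure(out, interval = iv))
  }
  EpochTable(out$time, iv, out["stage"])
}

#' Recover a hypnogram from summary records
#'
#' Convenience composition: expand all records to `targetInterval`, then
#' merge with the short-wins rule.
#'
#' @inheritParams expandRecords
#' @return an [EpochTable-class] of stages.
#' @export
recordsToHypnogram <- function(records, targetInterval = 30) {
  mergeShortLong(expandRecords(records, targetInterval))
}

#' Floor-align timestamps to a coarser grid
#'
#' Replaces each timestamp by its floor on a `gridInterval` grid (e.g.
#' 06:00:30 on a 60 s grid becomes 06:00:00), resolving the off-grid
#' measurement instants that would otherwise drop out of a natural join.
#' Several rows landing in one grid cell keep the earliest row (the stage is
#' assumed constant within a cell).
#'
#' @param table an [EpochTable-class] or a `data.frame` with a `time` column.
#' @param gridInterval target grid, seconds; must be >= the source interval.
#' @return `data.frame` with floored, de-duplicated `time`.
#' @export
floorAlign <- function(table, gridInterval) {
  df <- if (is(table, "EpochTable")) as.data.frame(table) else table
  if (is(table, "EpochTable") && gridInterval < epochInterval(table))
    stop("gridInterval must be >= the table's interval")
  tt <- as.numeric(df$time)
  df$time <- as.POSIXct((tt %/% gridInterval) * gridInterval,
                        origin = "1970-01-01", tz = "UTC")
  df <- df[order(df$time), , drop = FALSE]
  df <- df[!duplicated(df$time), , drop = FALSE]   # keep earliest per cell
  rownames(df) <- NULL
  df
}

#' Natural join of epoch tables on timestamp
#'
#' Rows are the intersection of the tables' timestamps; columns are the
#' union. All tables must already be floor-aligned to one grid. A column
#' name appearing in two tables is an error.
#'
#' @param tables list of [EpochTable-class] objects or `time`-keyed frames.
#' @param interval grid interval of the result, seconds (defaults to the
#'   first table's interval when available).
#' @return `data.frame` keyed by `time`, sorted; 0 rows when the
#'   intersection is empty.
#' @export
naturalJoin <- function(tables, interval = NULL) {
  frames <- lapply(tables, function(t)
    if (is(t, "EpochTable")) as.data.frame(t) else t)
  if (is.null(interval)) {
    ivs <- vapply(tables, function(t)
      if (is(t, "EpochTable")) epochInterval(t) else NA_real_, numeric(1))
    interval <- ivs[!is.na(ivs)][1]
  }
  cols <- unlist(lapply(frames, function(f) setdiff(names(f), "time")))
  if (anyDuplicated(cols))
    stop("column name collision in join: ",
         paste(unique(cols[duplicated(cols)]), collapse = ", "))
  out <- frames[[1]]
  for (f in frames[-1]) out <- merge(out, f, by = "time")
  out <- out[order(out$time), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "interval") <- interval
  out
}

#' Drop rows containing any missing value
#'
#' @param table `data.frame` or [EpochTable-class].
#' @return the table without incomplete rows; the number removed is reported
#'   with `message()`.
#' @export
dropNullRows <- function(table) {
  df <- if (is(table, "EpochTable")) as.data.frame(table) else table
  keep <- stats::complete.cases(df)
  if (any(!keep)) message("removed ", sum(!keep), " row(s) with null cells")
  out <- df[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

## ---- instance schemas -----------------------------------------------------

.I1 <- c("patientId", "time", "levels", "mets", "calories", "distance",
         "elevation", "floors", "fairActive", "lightActive", "veryActive",
         "sedentary", "steps", "stage")
.I2 <- append(.I1, c("hr", "hrvCalc"), after = 13L)
## the device's HRV summary has four fields; the shipped schema tracks three
## so the column count matches the published instance inventory
.I3 <- append(.I2, c("rmssd", "fHigh", "fLow"), after = 15L)
.I4 <- append(.I3, "temperature", after = 18L)
.I5 <- append(.I4, "spo2", after = 19L)
.AW <- c("patientId", "steps", "time", "circadian", "cosine", "hr", "stage")

INSTANCE_SCHEMAS <- list(
  I1_act  = list(name = "I1_act",  featureNames = .I1, interval = 60),
  I2_hr   = list(name = "I2_hr",   featureNames = .I2, interval = 60),
  I3_hrv  = list(name = "I3_hrv",  featureNames = .I3, interval = 60),
  I4_temp = list(name = "I4_temp", featureNames = .I4, interval = 60),
  I5_spo2 = list(name = "I5_spo2", featureNames = .I5, interval = 60),
  AW      = list(name = "AW",      featureNames = .AW, interval = 30),
  MESA    = list(name = "MESA",    featureNames = .AW, interval = 15)
)

#' Named instance schemas
#'
#' The seven shipped instance schemas (column inventory and epoch interval):
#' the five nested wearable instances `I1_act` (14 cols @ 60 s) through
#' `I5_spo2` (21 cols @ 60 s), and the two validation-shaped instances
#' `AW` (7 cols @ 30 s) and `MESA` (7 cols @ 15 s). Column counts include
#' the patient id, time and stage columns. Each schema's columns are a
#' superset of its predecessor's.
#'
#' @param name schema name; omit to list all schemas.
#' @return a schema list (`name`, `featureNames`, `interval`) or, with no
#'   argument, the named list of all schemas.
#' @export
instanceSchema <- function(name) {
  if (missing(name)) return(INSTANCE_SCHEMAS)
  if (!name %in% names(INSTANCE_SCHEMAS))
    stop("unknown schema: ", name)
  INSTANCE_SCHEMAS[[name]]
}

#' Column-select a joined table into a named instance
#'
#' @param joined joined `data.frame` (from [naturalJoin()]) containing at
#'   least every schema column.
#' @param schema a schema from [instanceSchema()] or its name.
#' @return an [EpochTable-class] with `schemaId` set and columns ordered per
#'   the schema; errors naming the first missing feature otherwise.
#' @export
buildInstance <- function(joined, schema) {
  if (is.character(schema)) schema <- instanceSchema(schema)
  missingCols <- setdiff(schema$featureNames, c(names(joined), "time"))
  if (length(missingCols))
    stop("joined table lacks schema feature(s): ",
         paste(missingCols, collapse = ", "))
  want <- schema$featureNames
  df <- joined[, c("time", setdiff(want, "time")), drop = FALSE]
  epochTableFromFrame(df, schema$interval, schema$name)
}
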