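#' Construct a sensor stream
#'
#' A sensor stream is the object every pipeline stage transforms: a set of
#' named real-valued channels (e.g. `acc_x`, `gyro_z`) sampled at strictly
#' increasing millisecond timestamps, with a nominal sampling rate.
#'
#' @param timestamps numeric vector of millisecond timestamps, strictly
#'   increasing.
#' @param channels numeric matrix, one column per channel, `length(timestamps)`
#'   rows; column names are the channel names.
#' @param rate_hz nominal sampling rate in Hz (> 0).
#' @return an object of class `sensor_stream`.
#' @export
sensor_stream <- function(timestamps, channels, rate_hz) {
  channels <- as.matrix(channels)
  storage.mode(channels) <- "double"
  if (is.null(colnames(channels))) {
    stop("channels must have column names")
  }
  dimnames(channels) <- list(NULL, colnames(channels))
  if (length(timestamps) != nrow(channels)) {
    stop("timestamps and channels disagree in length: ",
         length(timestamps), " vs ", nrow(channels))
  }
  if (length(timestamps) > 1L && any(diff(timestamps) <= 0)) {
    stop("timestamps must be strictly increasing")
  }
  if (!is.numeric(rate_hz) || length(rate_hz) != 1L || rate_hz <= 0) {
    stop("rate_hz must be a single positive number")
  }
  structure(
    list(timestamps = as.numeric(timestamps), channels = channels,
         rate_hz = as.numeric(rate_hz)),
    class = "sensor_stream"
  )
}

#' @export
print.sensor_stream <- function(x, ...) {
  cat(sprintf("<sensor_stream> %d samples x %d channels @ %g Hz nominal\n",
              nrow(x$channels), ncol(x$channels), x$rate_hz))
  cat("  channels:", paste(colnames(x$channels), collapse = ", "), "\n")
  if (nrow(x$channels) > 0L) {
    cat(sprintf("  span: %.0f..%.0f ms\n",
                x$timestamps[1L], x$timestamps[length(x$timestamps)]))
  }
  invisible(x)
}

#' Number of samples in a stream
#' @param s a `sensor_stream`.
#' @return integer sample count.
#' @export
n_samples <- function(s) nrow(s$channels)

#' Construct a label track
#'
#' Ordered, non-overlapping activity intervals over sample indices.  All
#' indices are 0-based and half-open `[start, end)`.  Unlabeled spans are
#' permitted (simply absent from the table).
#'
#' @param start,end integer vectors of interval bounds (0-based, half-open).
#' @param activity character vector of activity names.
#' @return a data frame of class `label_track` with columns
#'   `start`, `end`, `activity`, sorted by `start`.
#' @export
label_track <- function(start = integer(), end = integer(),
                        activity = character()) {
  stopifnot(length(start) == length(end), length(end) == length(activity))
  df <- data.frame(start = as.integer(start), end = as.integer(end),
                   activity = as.character(activity),
                   stringsAsFactors = FALSE)
  df <- df[order(df$start), , drop = FALSE]
  rownames(df) <- NULL
  if (any(df$end <= df$start)) {
    bad <- which(df$end <= df$start)[1L]
    stop(sprintf("interval %d is empty or reversed: [%d, %d)",
                 bad, df$start[bad], df$end[bad]))
  }
  if (nrow(df) > 1L) {
    ov <- which(df$start[-1L] < df$end[-nrow(df)])
    if (length(ov)) {
      i <- ov[1L]
      stop(sprintf(
        "overlapping intervals: [%d, %d) '%s' and [%d, %d) '%s'",
        df$start[i], df$end[i], df$activity[i],
        df$start[i + 1L], df$end[i + 1L], df$activity[i + 1L]))
    }
  }
  class(df) <- c("label_track", "data.frame")
  df
}

#' Expand a label track to a per-sample label vector
#'
#' @param labels a `label_track`.
#' @param T total number of samples.
#' @param unlabeled token used for samples not covered by any interval.
#' @return character vector of length `T`.
#' @export
labels_to_trace <- function(labels, T, unlabeled = "unlabeled") {
  out <- rep.int(unlabeled, T)
  for (i in seq_len(nrow(labels))) {
    s <- max(labels$start[i], 0L)
    e <- min(labels$end[i], T)
    if (e > s) out[(s + 1L):e] <- labels$activity[i]
  }
  out
}

# HARuS raw activity id coding; 7..12 are postural transitions, which the
# framework drops.
.harus_activity_ids <- c(
  "1" = "walking", "2" = "walking_upstairs", "3" = "walking_downstairs",
  "4" = "sitting", "5" = "standing", "6" = "laying")

#' Read a sensor stream from a delimited text file
#'
#' Two dialects are supported.  `simple`: delimited text (comma or tab,
#' auto-detected) with a header row, first column `timestamp_ms`, remaining
#' columns named channels.  `harus_raw`: three space-separated columns
#' (x, y, z) with no timestamps, fixed 50 Hz; timestamps are synthesized and
#' channel names derived from the file name prefix (`acc_*` or `gyro_*`).
#'
#' Rows are sorted by timestamp; exactly duplicated timestamps are averaged
#' (with a warning).
#'
#' @param path file path.
#' @param dialect `"simple"` or `"harus_raw"`.
#' @param rate_hz nominal rate for the `simple` dialect (default inferred
#'   from median timestamp spacing) and fixed rate for `harus_raw`
#'   (default 50).
#' @return a [sensor_stream()].
#' @export
read_sensor_stream <- function(path, dialect = c("simple", "harus_raw"),
                               rate_hz = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "harus_raw") {
    df <- tryCatch(
      utils::read.table(path, header = FALSE, colClasses = "numeric"),
      error = function(e) stop("parse error in ", path, ": ",
                               conditionMessage(e)))
    if (ncol(df) != 3L) stop("harus_raw expects 3 columns, got ", ncol(df))
    rate <- if (is.null(rate_hz)) 50 else rate_hz
    sensor <- if (grepl("gyro", basename(path))) "gyro" else "acc"
    ch <- as.matrix(df)
    colnames(ch) <- paste0(sensor, c("_x", "_y", "_z"))
    ts <- round((seq_len(nrow(ch)) - 1L) * 1000 / rate)
    return(sensor_stream(ts, ch, rate))
  }
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- tryCatch(
    utils::read.table(path, header = TRUE, sep = sep, colClasses = "numeric",
                      check.names = FALSE),
    error = function(e) stop("parse error in ", path, ": ",
                             conditionMessage(e)))
  if (!"timestamp_ms" %in% names(df)) {
    stop("simple dialect requires a 'timestamp_ms' column; found: ",
         paste(names(df), collapse = ", "))
  }
  df <- df[order(df$timestamp_ms), , drop = FALSE]
  ts <- df$timestamp_ms
  ch <- as.matrix(df[setdiff(names(df), "timestamp_ms")])
  if (anyDuplicated(ts)) {
    warning("duplicated timestamps in ", basename(path), "; averaging")
    ch <- rowsum(ch, group = ts, reorder = TRUE) /
      as.vector(table(ts))
    ts <- sort(unique(ts))
  }
  if (length(ts) > 1L && any(diff(ts) <= 0)) {
    stop("non-monotone timestamps after sort/dedup in ", path)
  }
  rate <- if (!is.null(rate_hz)) rate_hz else {
    if (length(ts) > 1L) 1000 / stats::median(diff(ts)) else 1
  }
  sensor_stream(ts, ch, rate)
}

#' Write a sensor stream in the simple dialect
#'
#' @param s a `sensor_stream`.
#' @param path output file path.
#' @param sep field separator (default tab).
#' @return `path`, invisibly.
#' @export
write_sensor_stream <- function(s, path, sep = "\t") {
  df <- data.frame(timestamp_ms = s$timestamps, s$channels,
                   check.names = FALSE)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read activity labels
#'
#' `interval_table` dialect: delimited text with header columns
#' `start`, `end`, `activity` (0-based half-open sample indices).  Files with
#' five headerless integer columns are treated as the raw smartphone-study
#' layout `(experiment, user, activity_id, start_sample, end_sample)`;
#' activity ids 1-6 map to the six basic activities, ids 7-12 (postural
#' transitions) are dropped, and any other id is an error.
#'
#' @param path file path.
#' @param dialect currently `"interval_table"`.
#' @param experiment,user optional filters for the 5-column layout.
#' @return a [label_track()].
#' @export
read_labels <- function(path, dialect = "interval_table",
                        experiment = NULL, user = NULL) {
  dialect <- match.arg(dialect, "interval_table")
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(label_track())
  first_fields <- strsplit(trimws(lines[1L]), "[,\t ]+")[[1L]]
  five_col <- length(first_fields) == 5L &&
    !anyNA(suppressWarnings(as.numeric(first_fields)))
  if (five_col) {
    df <- utils::read.table(text = lines, header = FALSE)
    names(df) <- c("experiment", "user", "activity_id", "start", "end")
    if (!is.null(experiment)) df <- df[df$experiment == experiment, ]
    if (!is.null(user)) df <- df[df$user == user, ]
    df <- df[!(df$activity_id %in% 7:12), , drop = FALSE]
    unknown <- setdiff(unique(df$activity_id), as.integer(names(.harus_activity_ids)))
    if (length(unknown)) {
      stop("unknown activity id(s): ", paste(unknown, collapse = ", "),
           "; known ids: ", paste(names(.harus_activity_ids), collapse = ", "))
    }
    # raw label files use 1-based closed sample ranges
    return(label_track(df$start - 1L, df$end,
                       .harus_activity_ids[as.character(df$activity_id)]))
  }
  sep <- if (grepl("\t", lines[1L])) "\t" else ","
  df <- utils::read.table(text = lines, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  need <- c("start", "end", "activity")
  if (!all(need %in% names(df))) {
    stop("interval_table requires columns start,end,activity; found: ",
         paste(names(df), collapse = ", "))
  }
  label_track(df$start, df$end, df$activity)
}

#' Write a label track
#' @param labels a `label_track`.
#' @param path output file path.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, path, sep = "\t") {
  utils::write.table(as.data.frame(labels), path, sep = sep,
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
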