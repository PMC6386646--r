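#' Snap a sensor stream onto an exact sampling grid
#'
#' Places every sample onto the nearest point of an exact `grid_hz` grid
#' (period `1000/grid_hz` ms, anchored at the first sample's
#' floor-to-grid time).  The grid covers each input sample's nominal
#' sampling period half-open, so an ideal `r` Hz input snapped to a 50 Hz
#' grid occupies exactly `T * 50/r` grid points and has missing fraction
#' exactly `1 - r/50` (for `r` dividing 50).  Grid points receiving no
#' sample are flagged missing; points receiving more than one sample hold
#' the mean; an exact halfway tie goes to the earlier grid point.
#'
#' @param stream a [sensor_stream()].
#' @param grid_hz target grid rate in Hz (default 50).
#' @return a `gridded_stream`: a `sensor_stream` on the exact grid with an
#'   additional logical `missing_mask` (samples x channels) and the grid
#'   period in ms as `grid_period_ms`.
#' @export
snap_to_grid <- function(stream, grid_hz = 50) {
  T_in <- n_samples(stream)
  if (T_in == 0L) stop("cannot grid an empty stream")
  P <- 1000 / grid_hz
  ts <- stream$timestamps
  g0 <- floor(ts[1L] / P) * P
  nominal_period <- 1000 / stream$rate_hz
  end_excl <- ts[T_in] + nominal_period
  n_grid <- max(1L, as.integer(ceiling((end_excl - g0) / P - 1e-9)))
  grid_ts <- g0 + (seq_len(n_grid) - 1) * P
  # nearest grid point, halfway ties to the earlier point
  idx <- as.integer(ceiling((ts - g0) / P - 0.5))
  idx[idx < 0L] <- 0L
  idx[idx > n_grid - 1L] <- n_grid - 1L
  m <- ncol(stream$channels)
  vals <- matrix(NA_real_, n_grid, m, dimnames = list(NULL, colnames(stream$channels)))
  counts <- tabulate(idx + 1L, nbins = n_grid)
  sums <- rowsum(stream$channels, group = idx, reorder = TRUE)
  occupied <- sort(unique(idx)) + 1L
  vals[occupied, ] <- sums / counts[occupied]
  mask <- matrix(counts == 0L, n_grid, m,
                 dimnames = list(NULL, colnames(stream$channels)))
  out <- sensor_stream(grid_ts, ifelse(mask, 0, vals), grid_hz)
  out$channels[mask] <- NA_real_
  out$missing_mask <- mask
  out$grid_period_ms <- P
  class(out) <- c("gridded_stream", class(out))
  out
}

#' @export
print.gridded_stream <- function(x, ...) {
  NextMethod()
  cat(sprintf("  missing: %.1f%% of grid points\n",
              100 * mean(rowSums(x$missing_mask) == ncol(x$missing_mask))))
  invisible(x)
}

# OLS line through (t, v) pairs evaluated at t0; falls back to the mean
# when the design is degenerate (single point).
.local_line_at <- function(t, v, t0) {
  if (length(t) == 1L) return(v)
  tc <- t - mean(t)
  denom <- sum(tc^2)
  if (denom == 0) return(mean(v))
  slope <- sum(tc * v) / denom
  mean(v) + slope * (t0 - mean(t))
}

#' Fill missing grid points by local line fits
#'
#' Each masked point is filled by evaluating an ordinary-least-squares line
#' fitted through up to `side_window` non-missing neighbors on each side
#' (time vs value); at stream edges the available side alone is used.
#' Non-missing values are untouched.  The operation is idempotent.
#'
#' @param g a `gridded_stream` from [snap_to_grid()].
#' @param side_window maximum non-missing neighbors used per side (default 5).
#' @return a [sensor_stream()] on the same grid with no missing values
#'   (mask retained as attribute `filled_mask`).
#' @export
interpolate_missing <- function(g, side_window = 5L) {
  if (is.null(g$missing_mask)) stop("interpolate_missing expects a gridded_stream")
  ch <- g$channels
  ts <- g$timestamps
  for (j in seq_len(ncol(ch))) {
    miss <- which(g$missing_mask[, j])
    if (!length(miss)) next
    nm <- which(!g$missing_mask[, j])
    if (length(nm) < 2L) {
      stop("channel '", colnames(ch)[j], "' has fewer than 2 observed samples")
    }
    pos <- findInterval(miss, nm)   # index of last non-missing before each miss
    for (k in seq_along(miss)) {
      i <- miss[k]
      p <- pos[k]
      left <- nm[seq.int(max(1L, p - side_window + 1L), length.out = min(p, side_window))]
      if (p < length(nm)) {
        right <- nm[seq.int(p + 1L, min(length(nm), p + side_window))]
      } else {
        right <- integer()
      }
      nb <- c(left, right)
      ch[i, j] <- .local_line_at(ts[nb], g$channels[nb, j], ts[i])
    }
  }
  out <- sensor_stream(ts, ch, g$rate_hz)
  attr(out, "filled_mask") <- g$missing_mask
  out
}

#' Split a gridded stream at long all-channel gaps
#'
#' Runs of grid points at which every channel is missing and whose duration
#' strictly exceeds `max_gap_s` are discarded, splitting the stream into
#' chunks.  A gap of exactly `max_gap_s` is kept.  Per-channel gaps (some
#' channels observed) never split.
#'
#' @param g a `gridded_stream`.
#' @param max_gap_s maximum tolerated all-missing gap in seconds (default 10).
#' @return list of `gridded_stream` chunks in original order.
#' @export
truncate_gaps <- function(g, max_gap_s = 10) {
  all_missing <- rowSums(!g$missing_mask) == 0L
  r <- rle(all_missing)
  thresh <- max_gap_s * 1000 / g$grid_period_ms   # samples in max_gap_s
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cut <- r$values & (r$lengths > thresh + 1e-9)
  # group consecutive kept runs into chunks
  chunks <- list()
  cur <- integer()
  for (i in seq_along(r$lengths)) {
    if (cut[i]) {
      if (length(cur)) { chunks[[length(chunks) + 1L]] <- cur; cur <- integer() }
    } else {
      cur <- c(cur, starts[i]:ends[i])
    }
  }
  if (length(cur)) chunks[[length(chunks) + 1L]] <- cur
  lapply(chunks, function(ix) {
    out <- sensor_stream(g$timestamps[ix], g$channels[ix, , drop = FALSE],
                         g$rate_hz)
    out$channels[g$missing_mask[ix, , drop = FALSE]] <- NA_real_
    out$missing_mask <- g$missing_mask[ix, , drop = FALSE]
    out$grid_period_ms <- g$grid_period_ms
    class(out) <- c("gridded_stream", class(out))
    out
  })
}

#' Align an accelerometer and a gyroscope stream on a common grid
#'
#' Both streams are snapped to the same exact `grid_hz` grid (the grid
#' anchors are multiples of the grid period, so the two grids coincide),
#' restricted to their overlapping span, interpolated, and merged into a
#' single 6-channel stream.  Long gaps are the caller's business
#' ([truncate_gaps()] operates on the pre-interpolation masks).
#'
#' @param acc,gyro `sensor_stream`s with 3 channels each.  Channels named
#'   `x`, `y`, `z` are prefixed `acc_` / `gyro_`.
#' @param grid_hz common grid rate (default 50).
#' @param side_window interpolation neighborhood, see [interpolate_missing()].
#' @return a 6-channel [sensor_stream()] on the common grid; the combined
#'   missing mask of the overlap is kept as attribute `filled_mask`.
#' @export
align_sensors <- function(acc, gyro, grid_hz = 50, side_window = 5L) {
  rename <- function(s, prefix) {
    cn <- colnames(s$channels)
    if (all(cn %in% c("x", "y", "z"))) {
      colnames(s$channels) <- paste0(prefix, "_", cn)
    }
    s
  }
  acc <- rename(acc, "acc"); gyro <- rename(gyro, "gyro")
  ga <- snap_to_grid(acc, grid_hz)
  gg <- snap_to_grid(gyro, grid_hz)
  lo <- max(ga$timestamps[1L], gg$timestamps[1L])
  hi <- min(ga$timestamps[length(ga$timestamps)],
            gg$timestamps[length(gg$timestamps)])
  if (hi < lo) {
    stop(sprintf("no temporal overlap: acc spans %.0f..%.0f ms, gyro %.0f..%.0f ms",
                 acc$timestamps[1L], acc$timestamps[length(acc$timestamps)],
                 gyro$timestamps[1L], gyro$timestamps[length(gyro$timestamps)]))
  }
  clip <- function(g) {
    ix <- which(g$timestamps >= lo - 1e-9 & g$timestamps <= hi + 1e-9)
    out <- sensor_stream(g$timestamps[ix], g$channels[ix, , drop = FALSE], g$rate_hz)
    out$channels[g$missing_mask[ix, , drop = FALSE]] <- NA_real_
    out$missing_mask <- g$missing_mask[ix, , drop = FALSE]
    out$grid_period_ms <- g$grid_period_ms
    class(out) <- c("gridded_stream", class(out))
    out
  }
  ga <- clip(ga); gg <- clip(gg)
  ia <- interpolate_missing(ga, side_window)
  ig <- interpolate_missing(gg, side_window)
  ch <- cbind(ia$channels, ig$channels)
  out <- sensor_stream(ia$timestamps, ch, grid_hz)
  attr(out, "filled_mask") <- cbind(ga$missing_mask, gg$missing_mask)
  out
}
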