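# Canonical channel sets
.canonical_channels <- c("acc_x", "acc_y", "acc_z", "gyro_x", "gyro_y", "gyro_z")
.feature_stats <- c("mean", "std", "mad", "min", "max", "entropy")

#' Augment the 6 raw signals to 14
#'
#' Adds, to the six canonical channels, their six time-derivatives
#' (`*_jerk`, central differences divided by the sample period; one-sided
#' at the edges) and the two per-sensor Euclidean norms (`acc_norm`,
#' `gyro_norm`).
#'
#' @param s a [sensor_stream()] with exactly the channels
#'   `acc_x, acc_y, acc_z, gyro_x, gyro_y, gyro_z` (any order).
#' @return a 14-channel `sensor_stream`.
#' @export
augment_signals <- function(s) {
  cn <- colnames(s$channels)
  if (!setequal(cn, .canonical_channels)) {
    stop("augment_signals expects exactly channels ",
         paste(.canonical_channels, collapse = ", "),
         "; got ", paste(cn, collapse = ", "))
  }
  x <- s$channels[, .canonical_channels, drop = FALSE]
  n <- nrow(x)
  dt <- 1 / s$rate_hz
  jerk <- apply(x, 2L, function(v) {
    if (n == 1L) return(0)
    d <- numeric(n)
    if (n > 2L) d[2:(n - 1L)] <- (v[3:n] - v[1:(n - 2L)]) / (2 * dt)
    d[1L] <- (v[2L] - v[1L]) / dt
    d[n] <- (v[n] - v[n - 1L]) / dt
    d
  })
  colnames(jerk) <- paste0(.canonical_channels, "_jerk")
  acc_norm <- sqrt(rowSums(x[, 1:3, drop = FALSE]^2))
  gyro_norm <- sqrt(rowSums(x[, 4:6, drop = FALSE]^2))
  out <- s
  out$channels <- cbind(x, jerk, acc_norm = acc_norm, gyro_norm = gyro_norm)
  out
}

#' Shannon entropy of a non-negative weight vector
#'
#' The vector is normalized to a probability vector; entropy is
#' `-sum(p * log(p))` in nats, with zero bins contributing 0.
#'
#' @param v non-negative numeric vector with at least one positive entry.
#' @return entropy in nats (>= 0).
#' @export
shannon_entropy <- function(v) {
  if (any(v < 0)) stop("weights must be non-negative")
  s <- sum(v)
  if (s <= 0) stop("all-zero weight vector has no entropy")
  p <- v / s
  plp <- p * log(p)
  plp[p == 0] <- 0
  -sum(plp)
}

# entropy variant used inside feature extraction: a constant-zero vector
# (e.g. the spectrum of a constant segment) is degenerate and scored 0.
.entropy0 <- function(v) {
  s <- sum(v)
  if (s <= 0) return(0)
  p <- v / s
  plp <- p * log(p)
  plp[p == 0] <- 0
  -sum(plp)
}

#' Feature names of the 168-dimension segment feature vector
#'
#' @param channels channel names (default the 14 augmented channels).
#' @return character vector of `6 * length(channels) * 2` names, time-domain
#'   first (`<channel>_<stat>`), then frequency-domain
#'   (`<channel>_fft_<stat>`).
#' @export
feature_names <- function(channels = c(.canonical_channels,
                                       paste0(.canonical_channels, "_jerk"),
                                       "acc_norm", "gyro_norm")) {
  c(as.vector(t(outer(channels, .feature_stats, paste, sep = "_"))),
    as.vector(t(outer(paste0(channels, "_fft"), .feature_stats, paste, sep = "_"))))
}

#' Extract per-segment statistical features
#'
#' For each segment, six statistics (mean, SD, unscaled median absolute
#' deviation, min, max, entropy) are computed on each channel in both the
#' time domain (the raw samples) and the frequency domain (the one-sided
#' magnitude spectrum of the mean-removed segment, DC bin included).  With
#' the 14 augmented channels this yields 6 x 14 x 2 = 168 named features
#' per segment.  Time-domain entropy uses the absolute sample values as
#' weights; frequency-domain entropy is the spectral entropy.  Segments
#' may have different lengths; all six statistics are length-agnostic
#' summaries, so no zero-padding is applied.
#'
#' @param a an augmented [sensor_stream()] (or any multichannel stream).
#' @param segments a data frame with columns `start`, `end` (0-based,
#'   half-open) partitioning `[0, T)`, e.g. from [fixed_windows()] or the
#'   `segments` element of a [ggs()] fit; every segment must hold at least
#'   2 samples.
#' @return a data frame: `seg_id`, `start`, `end`, then one column per
#'   feature.
#' @export
segment_features <- function(a, segments) {
  if (nrow(segments) == 0L) stop("empty segmentation")
  T_ <- n_samples(a)
  if (any(segments$end - segments$start < 2L)) {
    bad <- which(segments$end - segments$start < 2L)[1L]
    stop(sprintf("segment %d [%d, %d) has fewer than 2 samples (SD undefined)",
                 bad, segments$start[bad], segments$end[bad]))
  }
  if (any(segments$start < 0L) || any(segments$end > T_)) {
    stop("segments exceed stream extent [0, ", T_, ")")
  }
  ch_names <- colnames(a$channels)
  nms <- feature_names(ch_names)
  out <- segment_features_cpp(a$channels, as.integer(segments$start),
                              as.integer(segments$end))
  colnames(out) <- nms
  if (any(!is.finite(out))) {
    bad <- colnames(out)[which(colSums(!is.finite(out)) > 0L)]
    stop("non-finite features produced: ", paste(bad, collapse = ", "))
  }
  data.frame(seg_id = seq_len(nrow(segments)) - 1L,
             start = segments$start, end = segments$end,
             out, check.names = FALSE)
}

#' Column names of the feature block of a feature data frame
#' @param F a feature data frame from [segment_features()].
#' @return character vector of feature column names.
#' @export
feature_columns <- function(F) setdiff(names(F), c("seg_id", "start", "end"))
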