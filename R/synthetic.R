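# Synthetic labeled activity streams.
#
# Each activity class is a stationary 6-channel process
#   x_t = mu_c + A_c * sin(2 pi f_c t + phase) + eps_t,  eps_t ~ MVN(0, Sigma_c)
# i.e. the piecewise-Gaussian structure the segmentation model assumes,
# plus a deliberate oscillatory component for the dynamic classes (real
# gait data oscillate, violating within-segment independence; the
# segmentation has to cope with that, so the simulator reproduces it).
# Static postures are low-variance constant-mean processes whose means
# encode device orientation; dynamic classes oscillate at gait-like
# frequencies with higher noise.  Units are g for the accelerometer and
# rad/s for the gyroscope.

#' Default activity class models
#'
#' Six classes: three static postures (`lying`, `sitting`, `standing`)
#' and three dynamic activities (`walking`, `stairs`, `running`).  Means
#' differ moderately relative to the noise so that very short windows are
#' genuinely ambiguous while long homogeneous segments are separable, and
#' the dynamic classes differ mainly in oscillation frequency and
#' amplitude.
#'
#' @return named list; each element has `mean` (6), `sd` (6, diagonal
#'   noise SD), `amp` (6, oscillation amplitude), `freq_hz` (0 for static
#'   postures).
#' @export
activity_models <- function() {
  ch <- .canonical_channels
  mk <- function(mean, sd, amp, freq_hz) {
    names(mean) <- names(sd) <- names(amp) <- ch
    list(mean = mean, sd = sd, amp = amp, freq_hz = freq_hz)
  }
  list(
    lying    = mk(c(0.90, 0.10, 0.20, 0.00, 0.00, 0.00),
                  rep(c(0.06, 0.05), each = 3),
                  rep(0, 6), 0),
    sitting  = mk(c(0.30, 0.20, 0.90, 0.00, 0.00, 0.00),
                  rep(c(0.10, 0.08), each = 3),
                  rep(0, 6), 0),
    standing = mk(c(0.10, 0.05, 1.00, 0.00, 0.00, 0.00),
                  rep(c(0.10, 0.08), each = 3),
                  rep(0, 6), 0),
    walking  = mk(c(0.10, 0.00, 0.95, 0.00, 0.00, 0.00),
                  rep(c(0.20, 0.30), each = 3),
                  c(0.25, 0.15, 0.30, 0.50, 0.40, 0.30), 1.8),
    stairs   = mk(c(0.15, 0.05, 0.90, 0.00, 0.00, 0.00),
                  rep(c(0.25, 0.35), each = 3),
                  c(0.35, 0.20, 0.40, 0.60, 0.45, 0.40), 1.4),
    running  = mk(c(0.10, 0.00, 1.00, 0.00, 0.00, 0.00),
                  rep(c(0.35, 0.50), each = 3),
                  c(0.80, 0.50, 0.90, 1.20, 0.90, 1.00), 2.8)
  )
}

#' Activity protocol
#'
#' @param activity character vector of activity names.
#' @param duration_s positive bout durations in seconds.
#' @param rate_hz sampling rate in Hz.
#' @return list of class `protocol`.
#' @export
protocol <- function(activity, duration_s, rate_hz = 10) {
  stopifnot(length(activity) == length(duration_s), all(duration_s > 0))
  structure(list(activity = as.character(activity),
                 duration_s = as.numeric(duration_s),
                 rate_hz = rate_hz), class = "protocol")
}

#' Smartwatch-study-like protocol (one long session per activity)
#'
#' Five activities for 10 minutes each plus running for 5 minutes at
#' 10 Hz, the session structure of a wrist-worn smartwatch protocol.
#' `scale` shrinks every duration proportionally for desk-scale
#' experiments.
#'
#' @param scale duration multiplier (default 1).
#' @param rate_hz sampling rate (default 10).
#' @return a [protocol()].
#' @export
breathe_like_protocol <- function(scale = 1, rate_hz = 10) {
  protocol(c("standing", "sitting", "lying", "walking", "stairs", "running"),
           c(600, 600, 600, 600, 600, 300) * scale, rate_hz)
}

#' Smartphone-study-like protocol (short scripted bouts, repeated)
#'
#' Equal-duration bouts of the six activities in a scripted order at
#' 50 Hz, mirroring a waist-worn smartphone protocol of ~20 s bouts.
#'
#' @param bout_s bout duration in seconds (default 20).
#' @param repeats number of passes over the six activities (default 2).
#' @param rate_hz sampling rate (default 50).
#' @return a [protocol()].
#' @export
harus_like_protocol <- function(bout_s = 20, repeats = 2, rate_hz = 50) {
  acts <- rep(c("standing", "sitting", "lying", "walking", "stairs",
                "running"), repeats)
  protocol(acts, rep(bout_s, length(acts)), rate_hz)
}

#' Simulate a labeled activity stream
#'
#' Generates one 6-channel stream following a protocol: within each bout
#' of class `c`, `x_t = mu_c + A_c sin(2 pi f_c t + phase) + eps_t` with
#' independent Gaussian noise `eps_t` (diagonal covariance from the class
#' SDs) and a random phase per bout and channel.  Timestamps are exact
#' multiples of `1000/rate_hz` ms.
#'
#' @param proto a [protocol()].
#' @param models class models, see [activity_models()].
#' @param seed integer seed.
#' @return list with `stream` (a [sensor_stream()]) and `labels`
#'   (a [label_track()] matching the protocol exactly).
#' @export
simulate_activity_stream <- function(proto, models = activity_models(),
                                     seed = 1L) {
  set.seed(seed)
  rate <- proto$rate_hz
  unknown <- setdiff(proto$activity, names(models))
  if (length(unknown)) stop("no model for activity: ",
                            paste(unknown, collapse = ", "))
  n_per <- as.integer(round(proto$duration_s * rate))
  if (any(n_per < 1L)) stop("bout shorter than one sample")
  blocks <- vector("list", length(n_per))
  offset <- 0L
  starts <- ends <- integer(length(n_per))
  for (i in seq_along(n_per)) {
    mdl <- models[[proto$activity[i]]]
    if (any(mdl$sd < 0)) stop("invalid (negative) noise SD for ",
                              proto$activity[i])
    if (mdl$freq_hz >= rate / 2) stop("oscillation frequency of ",
                                      proto$activity[i],
                                      " at or above Nyquist")
    n <- n_per[i]
    tt <- (seq_len(n) - 1L) / rate
    phase <- stats::runif(6, 0, 2 * pi)
    osc <- sapply(1:6, function(j) {
      mdl$amp[j] * sin(2 * pi * mdl$freq_hz * tt + phase[j])
    })
    noise <- sapply(1:6, function(j) stats::rnorm(n, 0, mdl$sd[j]))
    blocks[[i]] <- sweep(osc + noise, 2L, mdl$mean, "+")
    starts[i] <- offset; ends[i] <- offset + n
    offset <- offset + n
  }
  ch <- do.call(rbind, blocks)
  colnames(ch) <- .canonical_channels
  ts <- round((seq_len(offset) - 1L) * 1000 / rate)
  list(stream = sensor_stream(ts, ch, rate),
       labels = label_track(starts, ends, proto$activity))
}

#' Subdivide and shuffle activity sessions
#'
#' Implements the artificial variable-bout construction: each labeled
#' session is split at `n_sub - 1` uniform-random interior cut points into
#' `n_sub` non-empty subsessions; all subsessions are then permuted
#' uniformly at random and concatenated, carrying their labels along.
#' Adjacent same-activity subsessions are merged in the output label
#' track, so the output may have fewer distinct bouts than subsessions.
#' Sample counts per activity are conserved exactly.
#'
#' @param stream a [sensor_stream()].
#' @param labels a [label_track()] covering the stream's sessions.
#' @param n_sub subsessions per session (default 10).
#' @param seed integer seed.
#' @return list with `stream`, `labels` and `n_subsessions` (total
#'   subsession count before concatenation); the permuted subsession
#'   blocks are attached as attribute `blocks` (data frame `activity`,
#'   `length`).
#' @export
shuffle_bouts <- function(stream, labels, n_sub = 10L, seed = 1L) {
  set.seed(seed)
  n_sub <- as.integer(n_sub)
  pieces <- list()
  for (i in seq_len(nrow(labels))) {
    s <- labels$start[i]; e <- labels$end[i]
    len <- e - s
    if (len < n_sub) {
      stop(sprintf("session %d ('%s', %d samples) too short for %d subsessions",
                   i, labels$activity[i], len, n_sub))
    }
    cuts <- if (n_sub > 1L) sort(sample(seq_len(len - 1L), n_sub - 1L)) else integer()
    bounds <- c(0L, cuts, len)
    for (k in seq_len(n_sub)) {
      ix <- (s + bounds[k] + 1L):(s + bounds[k + 1L])
      pieces[[length(pieces) + 1L]] <-
        list(activity = labels$activity[i],
             values = stream$channels[ix, , drop = FALSE])
    }
  }
  perm <- sample(length(pieces))
  pieces <- pieces[perm]
  ch <- do.call(rbind, lapply(pieces, `[[`, "values"))
  lens <- vapply(pieces, function(p) nrow(p$values), integer(1))
  acts <- vapply(pieces, `[[`, character(1), "activity")
  ends <- cumsum(lens)
  starts <- ends - lens
  # merge adjacent same-activity subsessions
  grp <- cumsum(c(TRUE, acts[-1L] != acts[-length(acts)]))
  m_start <- as.integer(tapply(starts, grp, min))
  m_end <- as.integer(tapply(ends, grp, max))
  m_act <- tapply(acts, grp, `[`, 1L)
  ts <- round((seq_len(sum(lens)) - 1L) * 1000 / stream$rate_hz)
  out <- list(stream = sensor_stream(ts, ch, stream$rate_hz),
              labels = label_track(m_start, m_end, as.character(m_act)),
              n_subsessions = length(pieces))
  attr(out, "blocks") <- data.frame(activity = acts, length = lens,
                                    stringsAsFactors = FALSE)
  out
}

#' Degrade a clean stream into realistic per-sensor files
#'
#' Splits a 6-channel stream into accelerometer and gyroscope halves and
#' injects acquisition artifacts: independent Gaussian timestamp jitter
#' per sensor, a constant inter-sensor clock offset added to the
#' gyroscope, and a number of missing spans removed from both sensors.
#' With all artifact magnitudes zero the two halves re-align exactly.
#'
#' @param stream a 6-channel [sensor_stream()].
#' @param jitter_ms SD of per-sample timestamp jitter in ms (default 0).
#' @param missing_spans `c(count, mean_duration_s)`: number of missing
#'   spans and their mean duration (exponential); default none.
#' @param sensor_offset_ms constant timestamp offset of the gyroscope.
#' @param seed integer seed.
#' @return list with `acc` and `gyro` [sensor_stream()]s.
#' @export
degrade_stream <- function(stream, jitter_ms = 0, missing_spans = c(0, 0),
                           sensor_offset_ms = 0, seed = 1L) {
  set.seed(seed)
  T_ <- n_samples(stream)
  drop <- rep(FALSE, T_)
  n_spans <- as.integer(missing_spans[1L])
  if (n_spans > 0L) {
    span_len <- pmax(1L, as.integer(round(
      stats::rexp(n_spans, 1 / missing_spans[2L]) * stream$rate_hz)))
    free <- T_ - sum(span_len)
    if (free < n_spans + 1L) stop("requested missing spans exceed stream length")
    # non-overlapping placement with at least one kept sample between spans
    offs <- sort(sample.int(free, n_spans))
    starts <- offs + c(0L, cumsum(span_len[-n_spans]))
    for (i in seq_len(n_spans)) {
      drop[starts[i]:(starts[i] + span_len[i] - 1L)] <- TRUE
    }
  }
  one_sensor <- function(cols, offset) {
    ts <- stream$timestamps + offset
    if (jitter_ms > 0) ts <- ts + round(stats::rnorm(T_, 0, jitter_ms))
    keep <- !drop
    ts <- ts[keep]
    vals <- stream$channels[keep, cols, drop = FALSE]
    o <- order(ts)
    ts <- ts[o]; vals <- vals[o, , drop = FALSE]
    if (anyDuplicated(ts)) {
      vals <- rowsum(vals, group = ts, reorder = TRUE) / as.vector(table(ts))
      ts <- sort(unique(ts))
    }
    sensor_stream(ts, vals, stream$rate_hz)
  }
  acc <- one_sensor(grep("^acc", colnames(stream$channels)), 0)
  gyro <- one_sensor(grep("^gyro", colnames(stream$channels)),
                     sensor_offset_ms)
  list(acc = acc, gyro = gyro)
}
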