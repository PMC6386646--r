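#' Desk-scale segmentation benchmark
#'
#' Generates a complete synthetic study — training and held-out test
#' streams — and runs [window_size_sweep()] on it, comparing greedy
#' Gaussian segmentation against fixed-size sliding windows on identical
#' instantaneous test samples.
#'
#' Two conditions are shipped.  `"shuffled_bouts"` emulates a smartwatch
#' study with artificially variable bout durations: per stream, one
#' session per activity (10 Hz; five activities plus a half-length running
#' session) is subdivided into 10 random subsessions each and the 60
#' subsessions are shuffled and concatenated; the sweep uses six window
#' sizes and tree depth 3.  `"equal_bouts"` emulates a scripted smartphone
#' protocol of equal-duration bouts at 50 Hz; four window sizes, tree
#' depth 2.  Session/bout durations default to desk-scale values (30 s
#' sessions, 8 s bouts) so a multi-seed run completes in minutes; the
#' relative ordering of methods, not absolute accuracy, is the quantity of
#' interest.
#'
#' @param condition `"shuffled_bouts"` or `"equal_bouts"`.
#' @param n_train,n_test number of training / held-out streams
#'   (default 12 / 2).
#' @param seed integer master seed; all stream and shuffle seeds derive
#'   from it.
#' @param scale session-duration multiplier for the shuffled condition
#'   (default 0.05 of the full 10-minute sessions).
#' @param bout_s,repeats bout duration and protocol repeats for the
#'   equal condition.
#' @return the [window_size_sweep()] result (data frame `method`,
#'   `size_s`, `accuracy_pct` with attribute `details`).
#' @export
har_benchmark <- function(condition = c("shuffled_bouts", "equal_bouts"),
                          n_train = 12L, n_test = 2L, seed = 1L,
                          scale = 0.05, bout_s = 8, repeats = 2L) {
  condition <- match.arg(condition)
  make <- function(i) {
    if (condition == "shuffled_bouts") {
      sim <- simulate_activity_stream(breathe_like_protocol(scale = scale),
                                      seed = seed * 1000L + i)
      sh <- shuffle_bouts(sim$stream, sim$labels, n_sub = 10L,
                          seed = seed * 1000L + 500L + i)
      list(stream = sh$stream, labels = sh$labels)
    } else {
      sim <- simulate_activity_stream(
        harus_like_protocol(bout_s = bout_s, repeats = repeats),
        seed = seed * 1000L + i)
      list(stream = sim$stream, labels = sim$labels)
    }
  }
  train <- lapply(seq_len(n_train), make)
  test <- lapply(n_train + seq_len(n_test), make)
  if (condition == "shuffled_bouts") {
    window_size_sweep(train, test, sizes_s = c(0.2, 0.8, 3, 8, 12, 40),
                      cutoff_hz = 4, spec = model_spec(max_depth = 3L))
  } else {
    window_size_sweep(train, test, sizes_s = c(0.2, 0.8, 3, 8),
                      cutoff_hz = 20, spec = model_spec(max_depth = 2L))
  }
}
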