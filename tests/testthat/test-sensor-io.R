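test_that("simple-dialect files round-trip exactly", {
  s <- six_channel_stream(matrix(rnorm(60), 10), rate_hz = 50)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_sensor_stream(s, f)
  r <- read_sensor_stream(f, "simple")
  expect_equal(r$timestamps, s$timestamps)
  expect_equal(r$channels, s$channels)
  expect_equal(r$rate_hz, 50)
})

test_that("reading averages duplicated timestamps with a warning", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("timestamp_ms,acc_x", "0,1", "20,2", "20,4", "40,7"), f)
  expect_warning(s <- read_sensor_stream(f, "simple"), "averaging")
  expect_equal(as.vector(s$channels), c(1, 3, 7))
  expect_equal(s$timestamps, c(0, 20, 40))
})

test_that("harus_raw dialect synthesizes 50 Hz timestamps and channel names", {
  f <- file.path(withr::local_tempdir(), "acc_exp01_user01.txt")
  writeLines(c("0.1 0.2 0.3", "0.4 0.5 0.6", "0.7 0.8 0.9"), f)
  s <- read_sensor_stream(f, "harus_raw")
  expect_equal(colnames(s$channels), c("acc_x", "acc_y", "acc_z"))
  expect_equal(s$timestamps, c(0, 20, 40))
})

test_that("label reading validates intervals", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("start,end,activity", "0,100,walking", "100,200,sitting"), f)
  lt <- read_labels(f)
  expect_s3_class(lt, "label_track")
  expect_equal(nrow(lt), 2L)

  writeLines(c("start,end,activity", "0,100,walking", "50,150,sitting"), f)
  expect_error(read_labels(f), "overlapping")

  writeLines(character(), f)
  expect_equal(nrow(read_labels(f)), 0L)
})

test_that("five-column raw label rows map ids, drop transitions, reject unknown ids", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("1 1 1 1 100", "1 1 7 101 120", "1 1 4 121 200"), f)
  lt <- read_labels(f)
  expect_equal(lt$activity, c("walking", "sitting"))
  expect_equal(lt$start, c(0L, 120L))
  writeLines("1 1 13 1 10", f)
  expect_error(read_labels(f), "unknown activity id")
})

test_that("ideal sub-rate input snapped to 50 Hz has exactly 1 - r/50 missing", {
  for (r in c(10, 25)) {
    T_in <- 40
    s <- toy_stream(rnorm(T_in), rate_hz = r)
    g <- snap_to_grid(s, 50)
    expect_equal(nrow(g$channels), T_in * 50 / r)
    expect_equal(mean(g$missing_mask), 1 - r / 50)
    expect_equal(g$channels[!g$missing_mask[, 1], 1], s$channels[, 1],
                 ignore_attr = TRUE)
  }
})

test_that("on-grid input snaps unchanged with nothing missing", {
  s <- toy_stream(rnorm(20), rate_hz = 50)
  g <- snap_to_grid(s, 50)
  expect_equal(mean(g$missing_mask), 0)
  expect_equal(g$channels, s$channels)
})

test_that("snap averages colliding samples and conserves mass", {
  # two samples nearest the same grid point -> mean
  ch <- matrix(c(1, 5, 9), dimnames = list(NULL, "acc_x"))
  s <- sensor_stream(c(0, 8, 40), ch, 50)
  g <- snap_to_grid(s, 50)
  expect_equal(unname(g$channels[1, 1]), 3)  # (1+5)/2 snapped to t=0 grid point
  # mass conservation: non-missing grid points <= input samples
  for (seed in 1:5) {
    set.seed(seed)
    ts <- sort(sample(0:400, 25))
    ts <- ts[c(TRUE, diff(ts) > 0)]
    s <- sensor_stream(ts, matrix(rnorm(length(ts)),
                                  dimnames = list(NULL, "acc_x")), 10)
    g <- snap_to_grid(s, 50)
    expect_lte(sum(!g$missing_mask[, 1]), length(ts))
  }
})

test_that("interpolation reproduces lines exactly and matches a per-point refit oracle", {
  # linear ramp: filled values lie on the ramp
  T_in <- 30
  ramp <- 0.5 + 0.25 * (0:(T_in - 1))
  s <- toy_stream(ramp, rate_hz = 10)
  g <- snap_to_grid(s, 50)
  f <- interpolate_missing(g)
  expect_equal(f$channels[, 1], 0.5 + 0.25 * (0:(nrow(f$channels) - 1)) / 5,
               tolerance = 1e-9, ignore_attr = TRUE)

  # quadratic signal, random mask: brute-force local-line refit per point
  set.seed(42)
  n <- 120
  v <- (seq_len(n) / 10)^2
  mask <- rep(FALSE, n)
  mask[sample(2:(n - 1), 50)] <- TRUE
  g <- snap_to_grid(toy_stream(v, 50), 50)
  g$missing_mask[, 1] <- mask
  g$channels[mask, 1] <- NA
  f <- interpolate_missing(g, side_window = 5)
  nm <- which(!mask)
  for (i in which(mask)) {
    left <- utils::tail(nm[nm < i], 5)
    right <- utils::head(nm[nm > i], 5)
    nb <- c(left, right)
    fit <- stats::lm(y ~ t, data.frame(t = g$timestamps[nb], y = v[nb]))
    expect_equal(unname(f$channels[i, 1]),
                 unname(stats::predict(fit, data.frame(t = g$timestamps[i]))),
                 tolerance = 1e-8)
  }
  # untouched where observed
  expect_equal(f$channels[nm, 1], v[nm], ignore_attr = TRUE)
})

test_that("interpolation is idempotent and errors on an empty channel", {
  s <- toy_stream(rnorm(30), rate_hz = 10)
  g <- snap_to_grid(s, 50)
  f1 <- interpolate_missing(g)
  g2 <- snap_to_grid(f1, 50)
  expect_equal(mean(g2$missing_mask), 0)
  f2 <- interpolate_missing(g2)
  expect_equal(f2$channels, f1$channels)

  g$missing_mask[, 1] <- TRUE
  g$channels[, 1] <- NA
  expect_error(interpolate_missing(g), "acc_x")
})

test_that("gap truncation follows the strictly-more-than rule", {
  mk_gap <- function(gap_samples) {
    n1 <- 50; n2 <- 40
    v <- rnorm(n1 + n2)
    s <- toy_stream(v, rate_hz = 50)
    g <- snap_to_grid(s, 50)
    # carve an all-missing gap inside
    total <- n1 + gap_samples + n2
    ch <- matrix(NA_real_, total, 1, dimnames = list(NULL, "acc_x"))
    ch[1:n1, 1] <- v[1:n1]; ch[(n1 + gap_samples + 1):total, 1] <- v[(n1 + 1):(n1 + n2)]
    g$timestamps <- (0:(total - 1)) * 20
    g$channels <- ch
    g$missing_mask <- matrix(is.na(ch), total, 1,
                             dimnames = list(NULL, "acc_x"))
    g
  }
  # 10.0 s exactly (500 samples at 50 Hz): NOT split
  expect_length(truncate_gaps(mk_gap(500)), 1L)
  # 11 s: split in two, lengths sum to input minus gap
  ck <- truncate_gaps(mk_gap(550))
  expect_length(ck, 2L)
  expect_equal(sum(vapply(ck, n_samples, integer(1))), 90L)
  # no gap: single chunk identical
  g <- snap_to_grid(toy_stream(rnorm(30), 50), 50)
  ck <- truncate_gaps(g)
  expect_length(ck, 1L)
  expect_equal(ck[[1]]$channels, g$channels)
})

test_that("chunks plus gaps reconstruct the original mask", {
  set.seed(7)
  n <- 800
  mask <- rep(FALSE, n)
  mask[100:700] <- TRUE     # 601 samples @50Hz = 12 s gap
  ch <- matrix(rnorm(n), dimnames = list(NULL, "acc_x"))
  ch[mask, 1] <- NA
  g <- snap_to_grid(toy_stream(ifelse(mask, 0, ch[, 1]), 50), 50)
  g$channels <- ch
  g$missing_mask <- matrix(mask, n, 1, dimnames = list(NULL, "acc_x"))
  ck <- truncate_gaps(g)
  rebuilt <- rep(TRUE, n)
  for (c_ in ck) {
    ix <- c_$timestamps / 20 + 1
    rebuilt[ix] <- c_$missing_mask[, 1]
  }
  expect_equal(rebuilt, mask)
})

test_that("sensor alignment merges identical-timestamp sensors as a column bind", {
  X <- matrix(rnorm(120), 20)
  s <- six_channel_stream(X, 50)
  acc <- sensor_stream(s$timestamps, s$channels[, 1:3], 50)
  gyro <- sensor_stream(s$timestamps, s$channels[, 4:6], 50)
  al <- align_sensors(acc, gyro, 50)
  expect_equal(al$channels, s$channels)
})

test_that("alignment recovers a jittered band-limited pair and rejects disjoint ranges", {
  set.seed(11)
  # truth must be near-linear over the ~1 s neighbor span the local-line
  # interpolation uses at 10 Hz, hence slow tones
  t_cont <- function(t) cbind(sin(2 * pi * 0.15 * t), cos(2 * pi * 0.1 * t),
                              sin(2 * pi * 0.2 * t))
  n <- 400
  ts <- (0:(n - 1)) * 100             # 10 Hz in ms
  mk <- function(prefix, jit, offset) {
    tj <- ts + offset + round(rnorm(n, 0, jit))
    tj <- sort(tj); tj <- tj[c(TRUE, diff(tj) > 0)]
    ch <- t_cont(tj / 1000)
    colnames(ch) <- paste0(prefix, c("_x", "_y", "_z"))
    sensor_stream(tj, ch, 10)
  }
  acc <- mk("acc", 4, 0); gyro <- mk("gyro", 4, 7)
  al <- align_sensors(acc, gyro, 50)
  truth <- cbind(t_cont(al$timestamps / 1000), t_cont(al$timestamps / 1000))
  rmse <- sqrt(colMeans((al$channels - truth)^2))
  expect_true(all(rmse < 0.05))

  late <- sensor_stream(ts + 1e6, acc$channels, 10)
  expect_error(align_sensors(late, gyro), "no temporal overlap")
})
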