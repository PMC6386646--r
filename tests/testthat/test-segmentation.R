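test_that("the objective is additive and invariant to channel permutation", {
  set.seed(21)
  X <- regime_stream(c(60, 60), c(0, 3), m = 4)
  phi <- ggs_objective(X, c(0, 60, 120), lambda = 0.5)
  psi_l <- oracle_psi(X[1:60, ], 0.5)
  psi_r <- oracle_psi(X[61:120, ], 0.5)
  expect_equal(phi, psi_l + psi_r, tolerance = 1e-9)

  expect_equal(ggs_objective(X[, c(3, 1, 4, 2)], c(0, 60, 120), lambda = 0.5),
               phi, tolerance = 1e-9)

  expect_error(ggs_objective(X, c(0, 2, 120), lambda = 0, min_seg_len = 5),
               "min_seg_len")
  expect_error(ggs_objective(X, c(0, 130), lambda = 0), "strictly increasing")
})

test_that("single-segment objective matches the closed form on i.i.d. Gaussian data", {
  set.seed(22)
  n <- 2000; m <- 6
  X <- matrix(rnorm(n * m), n)
  phi <- ggs_objective(X, c(0, n), lambda = 0)
  expect_equal(phi, -(n / 2) * m * (log(2 * pi) + 1), tolerance = 0.01)
  # and exactly equals the plug-in formula with the sample covariance
  S <- crossprod(sweep(X, 2, colMeans(X))) / n
  expect_equal(phi, -(n / 2) * (m * log(2 * pi) +
                                  determinant(S, TRUE)$modulus[1] + m),
               tolerance = 1e-9)
})

test_that("K = 1 greedy equals the exhaustive-split oracle exactly", {
  for (seed in 1:5) {
    X <- regime_stream(c(100, 100), c(0, 5), m = 2, seed = seed)
    fit <- ggs(X, K = 1, lambda = 0)
    oracle <- oracle_best_split(X, min_len = 5L, lambda = 0)
    expect_identical(fit$breakpoints[2], oracle$t)
    expect_equal(fit$objective, oracle$phi, tolerance = 1e-9)
  }
})

test_that("K = 0 returns the single segment", {
  X <- regime_stream(c(50), 0, m = 2)
  fit <- ggs(X, K = 0, lambda = 0)
  expect_equal(fit$breakpoints, c(0L, 50L))
  expect_equal(fit$objective, oracle_psi(X, 0), tolerance = 1e-9)
})

test_that("three-regime breakpoints are recovered within 2 samples in >= 95% of seeds", {
  hits <- 0L
  for (seed in 1:20) {
    X <- regime_stream(c(100, 100, 100), c(0, 5, 0), m = 2, seed = seed)
    fit <- ggs(X, K = 2, lambda = 0)
    bp <- sort(fit$breakpoints[2:3])
    if (all(abs(bp - c(100, 200)) <= 2)) hits <- hits + 1L
  }
  expect_gte(hits, 19L)
})

test_that("the adjustment phase is monotone in the objective", {
  set.seed(23)
  X <- regime_stream(c(80, 50, 120, 60), c(0, 2, -1, 1.5), m = 3)
  fit <- ggs(X, K = 6, lambda = 0.1, force_K = TRUE)
  expect_true(all(diff(fit$objective_trace) > -1e-9))
  expect_gte(fit$objective, fit$addition_curve[length(fit$addition_curve)] - 1e-9)
  # returned objective equals a recomputation on the returned breakpoints
  expect_equal(fit$objective, ggs_objective(X, fit$breakpoints, fit$lambda),
               tolerance = 1e-9)
})

test_that("breakpoints at lambda = 0 are invariant to positive channel scaling", {
  X <- regime_stream(c(70, 70, 70), c(0, 4, -4), m = 3, seed = 31)
  f1 <- ggs(X, K = 2, lambda = 0)
  f2 <- ggs(sweep(X, 2, c(2, 0.5, 7), "*"), K = 2, lambda = 0)
  expect_identical(f1$breakpoints, f2$breakpoints)
})

test_that("stronger regularization never increases the best first-split gain", {
  X <- regime_stream(c(60, 60), c(0, 1.5), m = 2, seed = 41)
  gain_at <- function(lam) {
    fit <- ggs(X, K = 1, lambda = lam, force_K = TRUE)
    fit$addition_curve[2] - fit$addition_curve[1]
  }
  gains <- vapply(c(0, 0.5, 2, 10, 50), gain_at, numeric(1))
  expect_true(all(diff(gains) <= 1e-9))
})

test_that("early stopping halts at non-positive gains unless forced", {
  set.seed(24)
  X <- matrix(rnorm(300 * 2), 300)   # homogeneous: splitting buys ~nothing
  fit <- ggs(X, K = 40, lambda = 50)
  expect_lt(fit$K, 40L)
  forced <- ggs(X, K = 10, lambda = 50, force_K = TRUE)
  expect_equal(forced$K, 10L)
})

test_that("the objective curve is consistent and finds the elbow on strong regimes", {
  X <- regime_stream(c(60, 60, 60), c(0, 5, 0), m = 2, seed = 51)
  cv <- objective_curve(X, K_max = 6, lambda = 0)
  expect_equal(nrow(cv), 7L)
  expect_equal(cv$K, 0:6)
  expect_true(all(diff(cv$objective) > -1e-9))

  # 12 true regimes with strong shifts: elbow within +/- 2 of K = 11
  set.seed(52)
  lens <- rep(60, 12)
  shifts <- rep(c(0, 6), 6)
  X12 <- regime_stream(lens, shifts, m = 3, seed = 52)
  cv12 <- objective_curve(X12, K_max = 20, lambda = 0)
  expect_lte(abs(attr(cv12, "elbow") - 11L), 2L)
})

test_that("infeasible requests error cleanly", {
  X <- matrix(rnorm(40), 20)
  expect_error(ggs(X, K = 5, lambda = 0, min_seg_len = 5), "infeasible")
  X[3, 1] <- NA
  expect_error(ggs(X, K = 1, lambda = 0), "non-finite")
})

test_that("fixed windows partition [0, T) under the documented tail rule", {
  w <- fixed_windows(500, 50, 2)
  expect_equal(nrow(w), 5L)
  expect_true(all(w$end - w$start == 100L))

  w <- fixed_windows(550, 50, 2)
  expect_equal(nrow(w), 6L)
  expect_equal(w$end[6] - w$start[6], 50L)

  expect_error(fixed_windows(100, 50, 0.02), "fewer than 2")

  set.seed(61)
  for (i in 1:25) {
    T_ <- sample(5:2000, 1)
    sz <- sample(c(0.2, 0.8, 3, 8), 1)
    r <- sample(c(10, 50), 1)
    if (T_ < 2 || round(sz * r) < 2) next
    w <- fixed_windows(T_, r, sz)
    expect_equal(w$start[1], 0L)
    expect_equal(w$end[nrow(w)], T_)
    if (nrow(w) > 1) expect_equal(w$start[-1], w$end[-nrow(w)])
    expect_true(all(w$end - w$start >= 2L))
  }
})
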