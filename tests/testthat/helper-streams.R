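# shared fixtures and independent oracles

# small stream on an exact grid
toy_stream <- function(values, rate_hz = 50, channels = "acc_x") {
  ch <- as.matrix(values)
  colnames(ch) <- channels
  sensor_stream(round((seq_len(nrow(ch)) - 1L) * 1000 / rate_hz), ch, rate_hz)
}

# 6-channel stream from a matrix
six_channel_stream <- function(X, rate_hz = 50) {
  colnames(X) <- c("acc_x", "acc_y", "acc_z", "gyro_x", "gyro_y", "gyro_z")
  sensor_stream(round((seq_len(nrow(X)) - 1L) * 1000 / rate_hz), X, rate_hz)
}

# independent segment Gaussian log-likelihood (direct formula, no prefix
# sums): plug-in mean, Sigma = S + (lambda/n) I, full log-likelihood
oracle_psi <- function(X, lambda = 0) {
  n <- nrow(X); m <- ncol(X)
  mu <- colMeans(X)
  S <- crossprod(sweep(X, 2, mu)) / n
  Sig <- S + diag(lambda / n, m)
  as.numeric(-0.5 * n * (m * log(2 * pi) +
                           determinant(Sig, logarithm = TRUE)$modulus +
                           sum(diag(solve(Sig, S)))))
}

oracle_objective <- function(X, b, lambda = 0) {
  sum(vapply(seq_len(length(b) - 1L), function(i) {
    oracle_psi(X[(b[i] + 1L):b[i + 1L], , drop = FALSE], lambda)
  }, numeric(1)))
}

# exhaustive best single split (the K = 1 global optimum)
oracle_best_split <- function(X, min_len = 5L, lambda = 0) {
  T_ <- nrow(X)
  cand <- seq.int(min_len, T_ - min_len)
  vals <- vapply(cand, function(t) oracle_objective(X, c(0L, t, T_), lambda),
                 numeric(1))
  list(t = cand[which.max(vals)], phi = max(vals))
}

# mean-shift stream with known breakpoints (unit noise, shift in every
# channel)
regime_stream <- function(lengths, shifts, m = 2L, seed = 1L) {
  set.seed(seed)
  do.call(rbind, lapply(seq_along(lengths), function(i) {
    matrix(stats::rnorm(lengths[i] * m, mean = shifts[i]), ncol = m)
  }))
}

# directly computed six statistics for one numeric vector (feature oracle)
oracle_stats <- function(v) {
  ent <- function(w) {
    s <- sum(w); if (s <= 0) return(0)
    p <- w / s; p <- p[p > 0]; -sum(p * log(p))
  }
  c(mean = mean(v), std = stats::sd(v),
    mad = stats::median(abs(v - stats::median(v))),
    min = min(v), max = max(v), entropy = ent(abs(v)))
}

oracle_spectrum <- function(v) {
  Mod(stats::fft(v - mean(v)))[seq_len(length(v) %/% 2 + 1)]
}

fixture_path <- function(name) system.file("extdata", name, package = "actiseg")
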