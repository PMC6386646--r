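# Greedy Gaussian segmentation (GGS).
#
# Model: within segment i, samples are i.i.d. MVN(mu_i, Sigma_i).  The
# fitted objective is the covariance-regularized log-likelihood
#   Phi(b) = sum_i psi_i,
#   psi_i  = Gaussian log-likelihood of segment i at mu_hat = sample mean
#            and Sigma_hat = S_i + (lambda/n_i) I,
# with S_i the biased sample covariance and n_i the segment length.  The
# regularizer keeps short noisy segments from producing singular
# covariances; lambda = 0 recovers the plain MLE plug-in likelihood.
# Segment likelihoods are evaluated from prefix sums in compiled code
# (src/ggs.cpp); this file owns the greedy control flow.

.ggs_prefix <- function(x) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (any(!is.finite(x))) stop("non-finite data")
  T_ <- nrow(x); m <- ncol(x)
  cx <- rbind(0, apply(x, 2L, cumsum))
  xx <- matrix(0, T_, m * m)
  for (i in seq_len(m)) for (j in seq_len(m)) {
    xx[, (i - 1L) * m + j] <- x[, i] * x[, j]
  }
  cxx <- rbind(0, apply(xx, 2L, cumsum))
  list(cx = cx, cxx = cxx, T = T_, m = m)
}

.default_lambda <- function(x) {
  v <- stats::median(apply(as.matrix(x), 2L, stats::var))
  if (!is.finite(v) || v <= 0) v <- 1
  1e-3 * v
}

#' Covariance-regularized segmentation objective
#'
#' Evaluates `Phi(b) = sum_i psi_i` for a given set of breakpoints, where
#' `psi_i` is the Gaussian log-likelihood of segment `i` at the sample
#' mean and the regularized covariance `S_i + (lambda/n_i) I`.  Additive
#' over segments by construction.
#'
#' @param x numeric sample matrix (rows = time, columns = channels).
#' @param b breakpoint vector including the endpoints: `0, ..., T`
#'   (0-based half-open segments `[b_i, b_{i+1})`), strictly increasing.
#' @param lambda regularization weight (>= 0); default
#'   `1e-3 * median(channel variances)`.
#' @param min_seg_len minimum admissible segment length (default 5).
#' @return the objective value `Phi(b)`.
#' @export
ggs_objective <- function(x, b, lambda = NULL, min_seg_len = 5L) {
  pre <- .ggs_prefix(x)
  if (is.null(lambda)) lambda <- .default_lambda(x)
  b <- as.integer(b)
  if (b[1L] != 0L || b[length(b)] != pre$T || any(diff(b) <= 0)) {
    stop("breakpoints must run 0 < ... < T strictly increasing with b[1]=0, b[last]=T")
  }
  if (any(diff(b) < min_seg_len)) {
    stop("segment shorter than min_seg_len (", min_seg_len, ")")
  }
  sum(vapply(seq_len(length(b) - 1L), function(i) {
    ggs_psi_cpp(pre$cx, pre$cxx, b[i], b[i + 1L], lambda)
  }, numeric(1)))
}

#' Greedy Gaussian segmentation
#'
#' Fits `K` breakpoints by the two-phase greedy heuristic.  Addition phase:
#' starting from no interior breakpoints, repeatedly insert the single
#' split (over all current segments and all admissible positions) with the
#' largest objective gain; by default the process stops early if the best
#' available gain is not positive (`force_K = TRUE` inserts all `K`
#' regardless, useful past the model-selection inflection).  Adjustment
#' phase: breakpoints are swept in order, each re-optimized within its two
#' flanking segments while the others are held fixed, until a full sweep
#' moves nothing.  Every accepted move strictly increases the objective,
#' so the procedure terminates.  Ties are broken toward the smallest
#' index.
#'
#' @inheritParams ggs_objective
#' @param K number of interior breakpoints requested.
#' @param force_K insert all `K` splits even when the best gain is <= 0.
#' @param adjust run the adjustment phase (default TRUE).
#' @return an object of class `ggs_segmentation`: list with `breakpoints`
#'   (length `K+2`, including 0 and `T`), `segments` (data frame `start`,
#'   `end`), `means` (list of per-segment mean vectors), `covariances`
#'   (list of regularized per-segment covariances), `objective`, `lambda`,
#'   `K`, `objective_trace` (objective after each accepted move, addition
#'   then adjustment) and `addition_curve` (objective after each addition,
#'   starting at `K = 0`).
#' @export
ggs <- function(x, K, lambda = NULL, min_seg_len = 5L, force_K = FALSE,
                adjust = TRUE) {
  x <- as.matrix(x)
  pre <- .ggs_prefix(x)
  if (is.null(lambda)) lambda <- .default_lambda(x)
  K <- as.integer(K)
  min_seg_len <- as.integer(min_seg_len)
  if (pre$T < (K + 1L) * min_seg_len) {
    stop(sprintf("infeasible K: T = %d < (K+1) * min_seg_len = %d",
                 pre$T, (K + 1L) * min_seg_len))
  }
  psi <- function(s, e) ggs_psi_cpp(pre$cx, pre$cxx, s, e, lambda)
  bsplit <- function(s, e) ggs_best_split_cpp(pre$cx, pre$cxx, s, e,
                                              min_seg_len, lambda)

  b <- c(0L, pre$T)
  seg_psi <- psi(0L, pre$T)
  seg_split <- list(bsplit(0L, pre$T))   # cached best split per segment
  phi <- sum(seg_psi)
  trace <- phi
  curve <- phi

  # ---- addition phase ----
  for (k in seq_len(K)) {
    gains <- vapply(seg_split, function(z) z[2L], numeric(1))
    if (all(!is.finite(gains) | gains == -Inf)) {
      if (force_K) stop("no admissible split remains before reaching K")
      break
    }
    best <- which.max(gains)           # ties -> earliest segment
    if (gains[best] <= 0 && !force_K) break
    sp <- seg_split[[best]]
    t_new <- as.integer(sp[1L])
    s <- b[best]; e <- b[best + 1L]
    b <- append(b, t_new, after = best)
    seg_psi <- append(seg_psi[-best], c(psi(s, t_new), psi(t_new, e)),
                      after = best - 1L)
    seg_split <- append(seg_split[-best],
                        list(bsplit(s, t_new), bsplit(t_new, e)),
                        after = best - 1L)
    phi <- sum(seg_psi)
    trace <- c(trace, phi)
    curve <- c(curve, phi)
  }

  # ---- adjustment phase ----
  if (adjust && length(b) > 2L) {
    tol <- 1e-9
    repeat {
      moved <- FALSE
      for (i in 2L:(length(b) - 1L)) {
        s <- b[i - 1L]; e <- b[i + 1L]
        cur <- seg_psi[i - 1L] + seg_psi[i]
        sp <- bsplit(s, e)
        t_new <- as.integer(sp[1L])
        if (t_new >= 0L && sp[3L] > cur + tol * (1 + abs(cur)) &&
            t_new != b[i]) {
          b[i] <- t_new
          seg_psi[i - 1L] <- psi(s, t_new)
          seg_psi[i] <- psi(t_new, e)
          phi <- sum(seg_psi)
          trace <- c(trace, phi)
          moved <- TRUE
        }
      }
      if (!moved) break
    }
  }

  segs <- data.frame(start = b[-length(b)], end = b[-1L])
  means <- covs <- vector("list", nrow(segs))
  for (i in seq_len(nrow(segs))) {
    X <- x[(segs$start[i] + 1L):segs$end[i], , drop = FALSE]
    n <- nrow(X)
    mu <- colMeans(X)
    S <- crossprod(sweep(X, 2L, mu)) / n
    means[[i]] <- mu
    covs[[i]] <- S + diag(lambda / n, pre$m)
  }
  structure(
    list(breakpoints = b, segments = segs, means = means, covariances = covs,
         objective = phi, lambda = lambda, K = length(b) - 2L,
         min_seg_len = min_seg_len, objective_trace = trace,
         addition_curve = curve),
    class = "ggs_segmentation")
}

#' @export
print.ggs_segmentation <- function(x, ...) {
  cat(sprintf("<ggs_segmentation> K = %d breakpoints over [0, %d), lambda = %.4g\n",
              x$K, x$breakpoints[length(x$breakpoints)], x$lambda))
  cat(sprintf("  objective Phi = %.4f\n", x$objective))
  invisible(x)
}

#' Objective-versus-K model-selection curve
#'
#' Records the objective after each greedy addition, from `K = 0` to
#' `K_max` (no adjustment phase, so the curve reflects the pure addition
#' path).  The suggested `K` is the elbow: the `K` maximizing the negative
#' second difference of the curve.
#'
#' @inheritParams ggs_objective
#' @param K_max largest breakpoint count to record.
#' @return data frame of class `ggs_curve` with columns `K`, `objective`,
#'   and attribute `elbow` (suggested `K`).
#' @export
objective_curve <- function(x, K_max, lambda = NULL, min_seg_len = 5L) {
  fit <- ggs(x, K = K_max, lambda = lambda, min_seg_len = min_seg_len,
             force_K = TRUE, adjust = FALSE)
  curve <- fit$addition_curve
  df <- data.frame(K = seq_along(curve) - 1L, objective = curve)
  elbow <- if (length(curve) >= 3L) {
    d2 <- diff(curve, differences = 2L)
    which.max(-d2)        # second difference at K = index
  } else NA_integer_
  attr(df, "elbow") <- as.integer(elbow)
  class(df) <- c("ggs_curve", "data.frame")
  df
}

#' Fixed-size non-overlapping windows
#'
#' Partitions `[0, T)` into consecutive windows of
#' `round(size_s * rate_hz)` samples.  A final partial window of at least
#' 2 samples is kept as its own window; a shorter remainder is merged into
#' the last full window, so the windows always partition `[0, T)` exactly.
#'
#' @param T total sample count.
#' @param rate_hz sampling rate in Hz.
#' @param size_s window size in seconds; `size_s * rate_hz` must be >= 2.
#' @return data frame with columns `start`, `end` (0-based, half-open).
#' @export
fixed_windows <- function(T, rate_hz, size_s) {
  w <- as.integer(round(size_s * rate_hz))
  if (w < 2L) stop("window of ", size_s, " s at ", rate_hz,
                   " Hz holds fewer than 2 samples")
  if (T < 2L) stop("stream too short to window")
  starts <- seq.int(0L, by = w, length.out = max(1L, T %/% w))
  ends <- pmin(starts + w, T)
  rem <- T - ends[length(ends)]
  if (rem >= 2L) {
    starts <- c(starts, ends[length(ends)])
    ends <- c(ends, T)
  } else if (rem > 0L) {
    ends[length(ends)] <- T
  }
  data.frame(start = as.integer(starts), end = as.integer(ends))
}
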