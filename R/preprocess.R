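#' Running-median outlier removal
#'
#' Replaces each channel by its running median of width `kernel`, with
#' reflect padding at the edges so that length is preserved.  A kernel of
#' 3 removes isolated single-sample spikes exactly.
#'
#' @param s a [sensor_stream()].
#' @param kernel odd window width (default 3).
#' @return a filtered `sensor_stream`.
#' @export
median_filter <- function(s, kernel = 3L) {
  kernel <- as.integer(kernel)
  if (kernel %% 2L == 0L || kernel < 1L) stop("kernel must be odd and >= 1")
  n <- n_samples(s)
  if (kernel > n) stop("kernel (", kernel, ") exceeds stream length (", n, ")")
  if (kernel == 1L || n == 1L) return(s)
  h <- (kernel - 1L) %/% 2L
  ch <- apply(s$channels, 2L, function(v) {
    pad <- c(v[(h + 1L):2L], v, v[(n - 1L):(n - h)])
    f <- stats::runmed(pad, kernel, endrule = "keep")
    f[(h + 1L):(h + n)]
  })
  out <- s
  out$channels <- ch
  out
}

# steady-state initial filter state for a unit step (companion-matrix
# solve), so edge transients vanish for signals approaching a constant
.lfilter_zi <- function(b, a) {
  n <- length(a)
  if (n == 1L) return(numeric())
  comp <- matrix(0, n - 1L, n - 1L)
  comp[1L, ] <- -a[-1L] / a[1L]
  if (n > 2L) comp[cbind(2:(n - 1L), 1:(n - 2L))] <- 1
  B <- b[-1L] - a[-1L] * b[1L]
  solve(diag(n - 1L) - t(comp), B)
}

# zero-phase filtering: odd extension at both ends, forward and backward
# passes with steady-state initial conditions, extension trimmed
.filtfilt <- function(b, a, x) {
  n <- length(x)
  padlen <- min(n - 1L, 3L * (max(length(a), length(b)) - 1L) * 10L)
  if (padlen < 1L) return(x)
  ext <- c(2 * x[1L] - x[(padlen + 1L):2L], x,
           2 * x[n] - x[(n - 1L):(n - padlen)])
  zi <- .lfilter_zi(b, a)
  y <- iir_df2t_cpp(b, a, ext, zi * ext[1L])
  y <- rev(iir_df2t_cpp(b, a, rev(y), zi * y[length(y)]))
  y[(padlen + 1L):(padlen + n)]
}

#' Zero-phase low-pass Butterworth filter
#'
#' Applies a digital low-pass Butterworth filter forward and backward
#' (two passes, zero net phase) to every channel.  The two-pass amplitude
#' response of the order-`order` bilinear design is
#' `1 / (1 + (tan(pi f / fs) / tan(pi fc / fs))^(2 order))`.
#' The pipeline is offline, so zero-phase filtering avoids shifting
#' features relative to the label track.
#'
#' @param s a [sensor_stream()].
#' @param order filter order (default 3).
#' @param cutoff_hz -3 dB cutoff frequency; must be below the Nyquist
#'   frequency `rate_hz/2`.
#' @return a filtered `sensor_stream` of identical length.
#' @export
butterworth_lowpass <- function(s, order = 3L, cutoff_hz = 20) {
  nyq <- s$rate_hz / 2
  if (cutoff_hz >= nyq) {
    stop(sprintf(
      "cutoff %.3g Hz is at or above Nyquist (%.3g Hz); resample to a higher rate first or skip filtering",
      cutoff_hz, nyq))
  }
  bf <- signal::butter(order, cutoff_hz / nyq, type = "low")
  out <- s
  out$channels <- apply(s$channels, 2L, function(v) .filtfilt(bf$b, bf$a, v))
  colnames(out$channels) <- colnames(s$channels)
  out
}

#' Welch power spectral density
#'
#' One-sided Welch estimate per channel: the stream is cut into
#' `nperseg`-sample segments with 50% overlap, each segment is mean-removed
#' and Hann-windowed, and the scaled periodograms are averaged.  The
#' estimate is density-scaled, so the integral of each curve over frequency
#' approximates the channel variance (Parseval).
#'
#' @param s a [sensor_stream()].
#' @param nperseg samples per segment (default 256, capped at the stream
#'   length is an error: the stream must be at least `nperseg` long).
#' @return an object of class `psd_curve`: list with `frequencies` (Hz) and
#'   `power` (matrix, one column per channel).
#' @export
psd_welch <- function(s, nperseg = 256L) {
  n <- n_samples(s)
  nperseg <- as.integer(nperseg)
  if (n < nperseg) {
    stop("stream length (", n, ") is shorter than nperseg (", nperseg, ")")
  }
  fs <- s$rate_hz
  step <- nperseg %/% 2L
  starts <- seq.int(1L, n - nperseg + 1L, by = step)
  w <- 0.5 * (1 - cos(2 * pi * (seq_len(nperseg) - 1L) / nperseg))  # periodic Hann
  U <- sum(w^2)
  nf <- nperseg %/% 2L + 1L
  pw <- matrix(0, nf, ncol(s$channels),
               dimnames = list(NULL, colnames(s$channels)))
  for (st in starts) {
    seg <- s$channels[st:(st + nperseg - 1L), , drop = FALSE]
    seg <- sweep(seg, 2L, colMeans(seg))
    Y <- stats::mvfft(seg * w)
    P <- Mod(Y[seq_len(nf), , drop = FALSE])^2 / (fs * U)
    # one-sided doubling, except DC and (for even nperseg) Nyquist
    dbl <- rep(2, nf); dbl[1L] <- 1
    if (nperseg %% 2L == 0L) dbl[nf] <- 1
    pw <- pw + P * dbl
  }
  pw <- pw / length(starts)
  structure(list(frequencies = (seq_len(nf) - 1L) * fs / nperseg, power = pw),
            class = "psd_curve")
}

#' @export
print.psd_curve <- function(x, ...) {
  cat(sprintf("<psd_curve> %d frequency bins (0..%.3g Hz) x %d channels\n",
              length(x$frequencies), max(x$frequencies), ncol(x$power)))
  invisible(x)
}

#' Write a PSD curve as tidy TSV (channel, freq_hz, power)
#' @param p a `psd_curve`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_psd <- function(p, path) {
  df <- do.call(rbind, lapply(colnames(p$power), function(ch) {
    data.frame(channel = ch, freq_hz = p$frequencies, power = p$power[, ch])
  }))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Standard preprocessing: median filter then zero-phase low-pass
#'
#' Convenience wrapper applying [median_filter()] and, when the cutoff is
#' feasible at the stream's rate, [butterworth_lowpass()].
#'
#' @param s a [sensor_stream()].
#' @param median_kernel running-median width (default 3).
#' @param butter_order Butterworth order (default 3).
#' @param cutoff_hz low-pass cutoff in Hz (default 20); skipped with a
#'   warning if at or above Nyquist.
#' @return a filtered `sensor_stream`.
#' @export
preprocess_stream <- function(s, median_kernel = 3L, butter_order = 3L,
                              cutoff_hz = 20) {
  s <- median_filter(s, median_kernel)
  if (cutoff_hz < s$rate_hz / 2) {
    s <- butterworth_lowpass(s, butter_order, cutoff_hz)
  } else {
    warning("cutoff ", cutoff_hz, " Hz >= Nyquist at ", s$rate_hz,
            " Hz; low-pass skipped")
  }
  s
}
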