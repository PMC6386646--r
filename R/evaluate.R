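#' Confusion matrix of instantaneous predictions
#'
#' Rows are true classes, columns predicted classes.  Samples whose truth
#' is the unlabeled token are excluded from the matrix and counted in the
#' `n_unlabeled` attribute.
#'
#' @param truth,pred character vectors of per-sample labels, equal length.
#' @param classes fixed class ordering; default sorted union of observed
#'   labels.
#' @param unlabeled token marking unscored truth samples.
#' @return integer matrix of class `confusion_matrix` with attribute
#'   `n_unlabeled`.
#' @export
confusion_matrix <- function(truth, pred, classes = NULL,
                             unlabeled = "unlabeled") {
  if (length(truth) != length(pred)) {
    stop("length mismatch: truth ", length(truth), ", pred ", length(pred))
  }
  keep <- truth != unlabeled
  n_unl <- sum(!keep)
  truth <- truth[keep]; pred <- pred[keep]
  if (is.null(classes)) classes <- sort(unique(c(truth, pred)))
  M <- table(factor(truth, levels = classes), factor(pred, levels = classes))
  M <- unclass(as.matrix(M))
  names(dimnames(M)) <- c("truth", "predicted")
  structure(M, class = c("confusion_matrix", class(M)), n_unlabeled = n_unl)
}

#' Read a confusion matrix from TSV
#'
#' Expects a header row of predicted class names (first column `truth`)
#' and one row per true class.  Two published instantaneous-prediction
#' confusion matrices ship with the package under `extdata`
#' (`harus_test_confusion.tsv`, `breathe_test_confusion.tsv`) for
#' arithmetic checks of the summary statistics.
#'
#' @param path TSV file path.
#' @return an integer matrix of class `confusion_matrix`.
#' @export
read_confusion <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  M <- as.matrix(df[, -1, drop = FALSE])
  rownames(M) <- df[[1]]
  storage.mode(M) <- "integer"
  names(dimnames(M)) <- c("truth", "predicted")
  structure(M, class = c("confusion_matrix", class(M)), n_unlabeled = 0L)
}

#' Summarize a confusion matrix
#'
#' Overall accuracy plus both per-class diagonal ratios, explicitly named:
#' `row_ratio` = diagonal / row total (the fraction of a true class
#' predicted correctly, conventionally recall) and `col_ratio` = diagonal /
#' column total (the fraction of a predicted class that is correct,
#' conventionally precision).  Both are reported under these neutral names
#' because published tables do not always follow the conventional naming.
#' Classes with a zero denominator are reported as `NA` (undefined), not 0.
#'
#' @param M a square count matrix (rows = truth), e.g. from
#'   [confusion_matrix()].
#' @return list with `accuracy_pct`, `row_ratio_pct`, `col_ratio_pct`
#'   (named per class), `total`.
#' @export
summarize_confusion <- function(M) {
  M <- as.matrix(M)
  if (nrow(M) != ncol(M)) stop("confusion matrix must be square")
  total <- sum(M)
  if (total <= 0) stop("empty confusion matrix")
  d <- diag(M)
  rs <- rowSums(M); cs <- colSums(M)
  rr <- ifelse(rs > 0, 100 * d / rs, NA_real_)
  cr <- ifelse(cs > 0, 100 * d / cs, NA_real_)
  names(rr) <- names(cr) <- rownames(M)
  list(accuracy_pct = 100 * sum(d) / total,
       row_ratio_pct = rr, col_ratio_pct = cr, total = total)
}

#' Instantaneous accuracy of a prediction trace
#' @param truth,pred per-sample label vectors.
#' @param unlabeled token excluded from scoring.
#' @return accuracy in percent.
#' @export
instantaneous_accuracy <- function(truth, pred, unlabeled = "unlabeled") {
  keep <- truth != unlabeled
  100 * mean(truth[keep] == pred[keep])
}

# preprocess + augment + featurize one stream against a window table
.featurize_windows <- function(stream, windows) {
  segment_features(augment_signals(stream), windows)
}

#' Run one segmentation method through the classification pipeline
#'
#' Shared harness: given preprocessed train/test streams with truth labels
#' and a window table per stream, extracts features, trains the classifier
#' on majority-labeled training segments, predicts test segments, and
#' scores instantaneous predictions on the test streams.
#'
#' @param train,test lists of `list(stream =, labels =)` entries; streams
#'   must already be preprocessed and carry the 6 canonical channels.
#' @param train_windows,test_windows lists of window tables (`start`,
#'   `end`), parallel to `train` / `test`.
#' @param spec a [model_spec()].
#' @param classes fixed class set.
#' @return list with `accuracy_pct`, `confusion`, `traces` (per test
#'   stream: `truth`, `pred`), `model`.
#' @keywords internal
run_windowed_pipeline <- function(train, test, train_windows, test_windows,
                                  spec = model_spec(), classes = NULL) {
  feats <- list(); labs <- character()
  for (i in seq_along(train)) {
    Ti <- n_samples(train[[i]]$stream)
    F <- .featurize_windows(train[[i]]$stream, train_windows[[i]])
    al <- assign_segment_labels(train_windows[[i]], train[[i]]$labels, Ti)
    keep <- !is.na(al$label)
    feats[[i]] <- F[keep, , drop = FALSE]
    labs <- c(labs, al$label[keep])
  }
  Ftrain <- do.call(rbind, feats)
  model <- train_classifier(Ftrain, labs, spec, classes)
  truth_all <- pred_all <- character()
  traces <- list()
  for (i in seq_along(test)) {
    Ti <- n_samples(test[[i]]$stream)
    F <- .featurize_windows(test[[i]]$stream, test_windows[[i]])
    p <- predict_segments(model, F)
    tr <- to_instantaneous(p$label, test_windows[[i]], Ti)
    tt <- labels_to_trace(test[[i]]$labels, Ti)
    traces[[i]] <- list(truth = tt, pred = tr)
    truth_all <- c(truth_all, tt); pred_all <- c(pred_all, tr)
  }
  M <- confusion_matrix(truth_all, pred_all, classes = model$classes)
  list(accuracy_pct = summarize_confusion(M)$accuracy_pct,
       confusion = M, traces = traces, model = model)
}

#' Accuracy sweep: fixed window sizes versus adaptive segmentation
#'
#' Runs the full classification pipeline once per fixed window size and
#' once with greedy Gaussian segmentation, scoring all methods
#' instantaneously on the identical held-out samples.  Streams are
#' preprocessed (median + zero-phase low-pass) before segmentation and
#' feature extraction; segmentation consumes the 6 original channels only.
#'
#' The per-stream breakpoint budget for the adaptive method is
#' `K = round(k_rate_per_min * duration_min)`, with `k_rate_per_min`
#' either supplied or calibrated on the training label tracks as 1.5x the
#' mean labeled bout rate (over-segmenting moderately, so noisy bouts
#' split into several segments rather than merging).
#'
#' @param train,test lists of `list(stream =, labels =)` raw streams with
#'   the 6 canonical channels.
#' @param sizes_s fixed window sizes in seconds.
#' @param cutoff_hz low-pass cutoff (skipped when infeasible at the
#'   stream rate).
#' @param k_rate_per_min breakpoints per minute for the adaptive method;
#'   `NULL` calibrates from the training labels.
#' @param lambda,min_seg_len segmentation settings, see [ggs()].
#' @param spec a [model_spec()].
#' @return data frame `method`, `size_s`, `accuracy_pct`; the adaptive row
#'   has `size_s = NA`.  The per-method pipeline results are attached as
#'   attribute `details`.
#' @export
window_size_sweep <- function(train, test, sizes_s = c(0.2, 0.8, 3, 8),
                              cutoff_hz = 20, k_rate_per_min = NULL,
                              lambda = NULL, min_seg_len = 5L,
                              spec = model_spec()) {
  prep <- function(entry) {
    s <- entry$stream
    s2 <- if (cutoff_hz < s$rate_hz / 2) {
      butterworth_lowpass(median_filter(s), cutoff_hz = cutoff_hz)
    } else {
      median_filter(s)
    }
    list(stream = s2, labels = entry$labels)
  }
  train <- lapply(train, prep); test <- lapply(test, prep)
  classes <- sort(unique(unlist(lapply(c(train, test),
                                       function(e) e$labels$activity))))
  if (is.null(k_rate_per_min)) {
    rates <- vapply(train, function(e) {
      dur_min <- n_samples(e$stream) / e$stream$rate_hz / 60
      nrow(e$labels) / dur_min
    }, numeric(1))
    k_rate_per_min <- 1.5 * mean(rates)
  }
  rows <- list(); details <- list()
  for (sz in sizes_s) {
    tw <- lapply(train, function(e) fixed_windows(n_samples(e$stream),
                                                  e$stream$rate_hz, sz))
    ew <- lapply(test, function(e) fixed_windows(n_samples(e$stream),
                                                 e$stream$rate_hz, sz))
    res <- run_windowed_pipeline(train, test, tw, ew, spec, classes)
    rows[[length(rows) + 1L]] <- data.frame(method = "fixed_w", size_s = sz,
                                            accuracy_pct = res$accuracy_pct)
    details[[paste0("fixed_", sz)]] <- res
  }
  seg_windows <- function(e) {
    x <- e$stream$channels[, .canonical_channels, drop = FALSE]
    dur_min <- n_samples(e$stream) / e$stream$rate_hz / 60
    K <- max(1L, as.integer(round(k_rate_per_min * dur_min)))
    fit <- ggs(x, K = K, lambda = lambda, min_seg_len = min_seg_len,
               force_K = TRUE)
    fit$segments
  }
  tw <- lapply(train, seg_windows)
  ew <- lapply(test, seg_windows)
  res <- run_windowed_pipeline(train, test, tw, ew, spec, classes)
  rows[[length(rows) + 1L]] <- data.frame(method = "ggs", size_s = NA_real_,
                                          accuracy_pct = res$accuracy_pct)
  details[["ggs"]] <- res
  out <- do.call(rbind, rows)
  attr(out, "details") <- details
  out
}
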