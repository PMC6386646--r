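#' Label segments from a ground-truth track
#'
#' Each segment receives the majority instantaneous label among its
#' labeled samples; ties go to the label occurring earliest within the
#' segment.  Purity is the majority fraction among labeled samples.
#' Segments whose samples are all unlabeled get `NA` and should be dropped
#' from training.
#'
#' @param segments data frame with `start`, `end` (0-based half-open),
#'   within `[0, T)`.
#' @param truth a [label_track()].
#' @param T total sample count.
#' @return data frame: `start`, `end`, `label` (NA if fully unlabeled),
#'   `purity`.
#' @export
assign_segment_labels <- function(segments, truth, T) {
  trace <- labels_to_trace(truth, T)
  lab <- character(nrow(segments))
  pur <- numeric(nrow(segments))
  for (i in seq_len(nrow(segments))) {
    v <- trace[(segments$start[i] + 1L):segments$end[i]]
    v <- v[v != "unlabeled"]
    if (!length(v)) { lab[i] <- NA_character_; pur[i] <- NA_real_; next }
    counts <- table(v)
    top <- max(counts)
    cand <- names(counts)[counts == top]
    if (length(cand) > 1L) {
      # earliest-occurring candidate within the segment
      first_pos <- vapply(cand, function(a) match(a, v), integer(1))
      cand <- cand[which.min(first_pos)]
    }
    lab[i] <- cand
    pur[i] <- top / length(v)
  }
  data.frame(start = segments$start, end = segments$end,
             label = lab, purity = pur, stringsAsFactors = FALSE)
}

#' Gradient-boosted-tree model specification
#'
#' Hyperparameters for the multiclass boosted-tree classifier.  The
#' shipped profiles mirror the two study set-ups: waist-worn smartphone
#' (`max_depth = 2`) and wrist-worn smartwatch (`max_depth = 3`); both use
#' 200 trees at learning rate 0.1 with no row or column subsampling.
#'
#' @param n_trees boosting rounds (default 200).
#' @param learning_rate shrinkage (default 0.1).
#' @param max_depth tree depth (default 3).
#' @param subsample,colsample row/column subsampling fractions (default 1).
#' @param seed integer seed for the booster.
#' @return a list of class `model_spec`.
#' @export
model_spec <- function(n_trees = 200L, learning_rate = 0.1, max_depth = 3L,
                       subsample = 1, colsample = 1, seed = 0L) {
  stopifnot(n_trees >= 1L, learning_rate > 0, learning_rate <= 1)
  structure(list(n_trees = as.integer(n_trees), learning_rate = learning_rate,
                 max_depth = as.integer(max_depth), subsample = subsample,
                 colsample = colsample, seed = as.integer(seed)),
            class = "model_spec")
}

#' Train the multiclass boosted-tree classifier
#'
#' Fits a gradient-boosted-tree model (soft-probability multiclass
#' objective) on a segment feature matrix.  Single-threaded and seeded, so
#' training is deterministic and invariant to row order.
#'
#' @param F feature data frame from [segment_features()] (or any data frame
#'   whose non-`seg_id`/`start`/`end` columns are the features).
#' @param y character/factor vector of segment labels, one per row of `F`.
#' @param spec a [model_spec()].
#' @param classes optional fixed class ordering; default sorted unique `y`.
#' @return an object of class `har_model`: list with the fitted booster,
#'   `classes` and `features`.
#' @export
train_classifier <- function(F, y, spec = model_spec(), classes = NULL) {
  X <- as.matrix(F[feature_columns(F)])
  y <- as.character(y)
  stopifnot(nrow(X) == length(y))
  if (any(!is.finite(X))) {
    bad <- colnames(X)[colSums(!is.finite(X)) > 0L]
    stop("non-finite feature column(s): ", paste(bad, collapse = ", "))
  }
  if (is.null(classes)) classes <- sort(unique(y))
  if (length(classes) < 2L) stop("need at least 2 classes, got: ",
                                 paste(classes, collapse = ", "))
  if (!all(y %in% classes)) stop("labels outside the class set: ",
                                 paste(setdiff(y, classes), collapse = ", "))
  # canonical row order (full lexicographic sort) so that training is
  # invariant to the order rows were supplied in
  key <- as.data.frame(cbind(start = F$start %||% rep(0, nrow(X)), X))
  ord <- do.call(order, key)
  X <- X[ord, , drop = FALSE]; y <- y[ord]
  d <- xgboost::xgb.DMatrix(X, label = match(y, classes) - 1L)
  booster <- xgboost::xgb.train(
    params = list(objective = "multi:softprob", num_class = length(classes),
                  eta = spec$learning_rate, max_depth = spec$max_depth,
                  subsample = spec$subsample, colsample_bytree = spec$colsample,
                  tree_method = "hist", nthread = 1L, seed = spec$seed),
    data = d, nrounds = spec$n_trees, verbose = 0)
  structure(list(booster = booster, classes = classes,
                 features = colnames(X), spec = spec),
            class = "har_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Predict per-segment activity labels
#'
#' @param model a `har_model` from [train_classifier()].
#' @param F feature data frame with the same feature columns as training.
#' @return data frame with `label` and one probability column per class
#'   (`prob_<class>`, rows summing to 1).
#' @export
predict_segments <- function(model, F) {
  fc <- feature_columns(F)
  missing_ <- setdiff(model$features, fc)
  extra <- setdiff(fc, model$features)
  if (length(missing_) || length(extra)) {
    stop("feature schema mismatch; missing: [",
         paste(missing_, collapse = ", "), "], extra: [",
         paste(extra, collapse = ", "), "]")
  }
  X <- as.matrix(F[model$features])
  probs <- stats::predict(model$booster, xgboost::xgb.DMatrix(X))
  probs <- matrix(probs, nrow = nrow(X), ncol = length(model$classes))
  colnames(probs) <- paste0("prob_", model$classes)
  lab <- model$classes[max.col(probs, ties.method = "first")]
  data.frame(label = lab, probs, stringsAsFactors = FALSE)
}

#' Broadcast segment predictions to instantaneous predictions
#'
#' Every sample of a segment receives that segment's label, yielding a
#' per-sample prediction trace of length `T` — the common currency for
#' comparing segmentation schemes.
#'
#' @param seg_labels character vector, one label per segment.
#' @param segments data frame `start`, `end` partitioning `[0, T)`.
#' @param T total sample count.
#' @param provenance tag stored on the trace (e.g. `"ggs"`, `"fixed_w"`).
#' @return character vector of length `T` with attribute `provenance`.
#' @export
to_instantaneous <- function(seg_labels, segments, T, provenance = "ggs") {
  if (length(seg_labels) != nrow(segments)) {
    stop("one label per segment required")
  }
  o <- order(segments$start)
  segments <- segments[o, , drop = FALSE]
  seg_labels <- seg_labels[o]
  if (segments$start[1L] != 0L || segments$end[nrow(segments)] != T ||
      (nrow(segments) > 1L &&
       any(segments$start[-1L] != segments$end[-nrow(segments)]))) {
    stop("segments do not partition [0, ", T, ")")
  }
  out <- rep.int(seg_labels, segments$end - segments$start)
  attr(out, "provenance") <- provenance
  out
}

#' Ranked feature importances
#'
#' Gain-based importance scores of the fitted booster, ranked.
#'
#' @param model a `har_model`.
#' @param top_n number of features to return (default 15).
#' @return data frame `feature`, `score`, scores non-increasing.
#' @export
feature_importances <- function(model, top_n = 15L) {
  imp <- xgboost::xgb.importance(model = model$booster)
  df <- data.frame(feature = imp$Feature, score = imp$Gain,
                   stringsAsFactors = FALSE)
  df <- df[order(-df$score), , drop = FALSE]
  utils::head(df, top_n)
}
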