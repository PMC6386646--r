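# small separable feature fixture: two Gaussian clusters per class in a
# handful of informative columns, the rest noise
make_separable <- function(n_per = 30, classes = c("a", "b", "c"),
                           shift = 6, seed = 1) {
  set.seed(seed)
  rows <- lapply(seq_along(classes), function(k) {
    X <- matrix(rnorm(n_per * 10), n_per)
    X[, k] <- X[, k] + shift * k
    X
  })
  X <- do.call(rbind, rows)
  colnames(X) <- paste0("f", 1:10)
  F <- data.frame(seg_id = seq_len(nrow(X)) - 1L,
                  start = (seq_len(nrow(X)) - 1L) * 10L,
                  end = seq_len(nrow(X)) * 10L, X, check.names = FALSE)
  list(F = F, y = rep(classes, each = n_per))
}

test_that("segment labeling uses majority vote with earliest-label tie-break", {
  truth <- label_track(c(0L, 100L), c(100L, 200L), c("walking", "sitting"))
  segs <- data.frame(start = c(0L, 40L, 60L), end = c(40L, 60L, 160L))
  al <- assign_segment_labels(segs, truth, 200L)
  # [60,160): 40 walking vs 60 sitting samples
  expect_equal(al$label, c("walking", "walking", "sitting"))
  expect_equal(al$purity, c(1, 1, 0.6))

  # 60/40 split
  segs <- data.frame(start = 40L, end = 140L)
  al <- assign_segment_labels(segs, truth, 200L)
  expect_equal(al$label, "walking")
  expect_equal(al$purity, 0.6)

  # 50/50 tie -> earliest within segment (sitting starts the segment here)
  truth2 <- label_track(c(0L, 50L), c(50L, 100L), c("sitting", "walking"))
  al <- assign_segment_labels(data.frame(start = 0L, end = 100L), truth2, 100L)
  expect_equal(al$label, "sitting")

  # fully unlabeled segment -> NA
  al <- assign_segment_labels(data.frame(start = 250L, end = 300L),
                              truth, 400L)
  expect_true(is.na(al$label))
})

test_that("training separates separable classes and is deterministic under row permutation", {
  fx <- make_separable()
  m <- train_classifier(fx$F, fx$y, model_spec(n_trees = 50, seed = 7))
  p <- predict_segments(m, fx$F)
  expect_equal(mean(p$label == fx$y), 1)
  expect_true(all(abs(rowSums(as.matrix(p[grep("^prob_", names(p))])) - 1) < 1e-6))

  set.seed(42)
  perm <- sample(nrow(fx$F))
  m2 <- train_classifier(fx$F[perm, ], fx$y[perm], model_spec(n_trees = 50, seed = 7))
  p2 <- predict_segments(m2, fx$F)
  expect_identical(p$label, p2$label)
  expect_equal(as.matrix(p[-1]), as.matrix(p2[-1]), tolerance = 1e-12)
})

test_that("training rejects degenerate inputs and schema mismatches", {
  fx <- make_separable()
  expect_error(train_classifier(fx$F, rep("a", nrow(fx$F))), "2 classes")
  bad <- fx$F; bad$f3[5] <- NA
  expect_error(train_classifier(bad, fx$y), "f3")

  m <- train_classifier(fx$F, fx$y, model_spec(n_trees = 20))
  F2 <- fx$F; names(F2)[names(F2) == "f1"] <- "g1"
  expect_error(predict_segments(m, F2), "missing: \\[f1\\]")
})

test_that("a shifted test cluster maps to its nearest training class", {
  fx <- make_separable(shift = 8)
  m <- train_classifier(fx$F, fx$y, model_spec(n_trees = 50))
  Ftest <- fx$F[1:10, ]
  Ftest$f2 <- Ftest$f2 + 16  # move into class b territory
  Ftest$f1 <- 0
  p <- predict_segments(m, Ftest)
  expect_true(all(p$label == "b"))
})

test_that("instantaneous broadcasting conserves length and weighted accuracy", {
  segs <- data.frame(start = c(0L, 30L, 80L), end = c(30L, 80L, 100L))
  tr <- to_instantaneous(c("walking", "sitting", "walking"), segs, 100L)
  expect_length(tr, 100L)
  expect_equal(unname(table(tr)["walking"]), 50L, ignore_attr = TRUE)

  # single segment -> constant trace
  tr1 <- to_instantaneous("running", data.frame(start = 0L, end = 40L), 40L)
  expect_equal(unique(tr1), "running")

  # instantaneous accuracy equals segment-length-weighted segment accuracy
  set.seed(31)
  truth_seg <- sample(c("a", "b"), 3, TRUE)
  truth <- to_instantaneous(truth_seg, segs, 100L)
  pred_seg <- c("a", "b", "a")
  pred <- to_instantaneous(pred_seg, segs, 100L)
  lens <- segs$end - segs$start
  expect_equal(instantaneous_accuracy(truth, pred),
               100 * sum(lens * (truth_seg == pred_seg)) / sum(lens))

  expect_error(to_instantaneous(c("a", "b"), segs, 100L), "one label")
  expect_error(to_instantaneous(c("a", "b", "c"), segs, 120L), "partition")
})

test_that("class renaming permutes outputs only", {
  fx <- make_separable(seed = 5)
  ren <- c(a = "zebra", b = "yak", c = "xerus")
  m1 <- train_classifier(fx$F, fx$y, model_spec(n_trees = 30, seed = 1))
  m2 <- train_classifier(fx$F, unname(ren[fx$y]), model_spec(n_trees = 30, seed = 1),
                         classes = unname(ren[sort(unique(fx$y))]))
  p1 <- predict_segments(m1, fx$F)
  p2 <- predict_segments(m2, fx$F)
  expect_identical(unname(ren[p1$label]), p2$label)
})

test_that("feature importances rank the informative feature first", {
  set.seed(13)
  n <- 60
  X <- matrix(rnorm(n * 5), n)
  colnames(X) <- c("acc_x_mean", paste0("noise", 1:4))
  y <- rep(c("p", "q"), each = n / 2)
  X[y == "q", 1] <- X[y == "q", 1] + 10
  F <- data.frame(seg_id = 0:(n - 1), start = 0:(n - 1), end = 1:n + 1L, X,
                  check.names = FALSE)
  m <- train_classifier(F, y, model_spec(n_trees = 30))
  imp <- feature_importances(m, top_n = 3)
  expect_equal(imp$feature[1], "acc_x_mean")
  expect_true(all(diff(imp$score) <= 0))
  expect_lte(nrow(imp), 3L)
})
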