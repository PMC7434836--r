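# small labeled feature tibble used across blocks
toy_features <- function(n = 40, seed = 21, bias = 2.5) {
  d <- simulate_peptides(n_pos = n / 2, n_neg = n / 2, bias = bias,
                         seed = seed)
  encode_aac(d)
}

test_that("rank_features matches a brute-force score computation on a hand matrix", {
  # 8 samples x 3 features, fixed by hand
  X <- cbind(f1 = c(0, 0, 1, 1, 0, 1, 1, 1),
             f2 = c(5, 3, 4, 1, 2, 6, 8, 7),
             f3 = c(1, 1, 1, 1, 1, 1, 1, 1))  # constant
  y <- c(0, 0, 0, 0, 1, 1, 1, 1)
  data <- dplyr::bind_cols(tibble::as_tibble(X), tibble::tibble(label = y))
  r <- rank_features(data)

  # independent oracle: per-feature |cor| and mean pairwise Euclidean
  # distance of unit-normalized z-scored columns, by explicit loops
  z <- apply(X, 2, function(col) {
    if (sd(col) == 0) rep(0, length(col)) else (col - mean(col)) / sd(col)
  })
  u <- apply(z, 2, function(col) {
    nr <- sqrt(sum(col^2)); if (nr == 0) col else col / nr
  })
  expected <- sapply(1:3, function(j) {
    rel <- if (sd(X[, j]) == 0) 0 else abs(cor(X[, j], y))
    dists <- c()
    for (k in setdiff(1:3, j)) {
      dists <- c(dists, sqrt(sum((u[, j] - u[, k])^2)))
    }
    rel + mean(dists)
  })
  names(expected) <- colnames(X)
  got <- setNames(r$score, r$feature)[colnames(X)]
  expect_equal(unname(got), unname(expected), tolerance = 1e-12)
  expect_equal(r$relevance[r$feature == "f3"], 0)  # zero-variance convention
  # scores non-increasing along the returned order
  expect_true(all(diff(r$score) <= 1e-12))
  # a permutation of the input features
  expect_setequal(r$feature, colnames(X))
})

test_that("a label-copy feature outranks noise and ranking ignores row order", {
  withr::with_seed(33, {
    y <- rep(c(0L, 1L), each = 15)
    data <- tibble::tibble(
      oracle = as.numeric(y),
      n1 = rnorm(30), n2 = rnorm(30), n3 = rnorm(30),
      label = y)
  })
  r <- rank_features(data)
  expect_equal(r$feature[1], "oracle")

  perm <- sample(seq_len(nrow(data)))
  r2 <- rank_features(data[perm, ])
  expect_equal(as.data.frame(r), as.data.frame(r2))

  expect_error(rank_features(dplyr::mutate(data, label = 0L)), "both classes")
})

test_that("incremental_curve is deterministic and consistent with cross_validate", {
  feats <- toy_features()
  curve <- incremental_curve(feats, folds = 5, seed = 7)
  expect_equal(curve$dimension, 1:20)
  expect_true(all(diff(curve$dimension) > 0))

  curve2 <- incremental_curve(feats, folds = 5, seed = 7)
  expect_identical(as.data.frame(curve), as.data.frame(curve2))

  # point at m = d equals a direct pooled CV on the full matrix, same seed
  full <- cross_validate(feats, folds = 5, seed = 7)
  last <- curve[nrow(curve), ]
  expect_equal(last$acc, full$metrics$acc)
  expect_equal(last$f_score, full$metrics$f_score)
  expect_equal(last$mcc, full$metrics$mcc)

  # d = 1 degenerate curve
  one <- incremental_curve(feats[, c("id", "K", "label")], folds = 5, seed = 1)
  expect_equal(nrow(one), 1L)
})

test_that("select_best returns the smallest F-score-maximizing dimension", {
  fake_curve <- function(f) {
    structure(tibble::tibble(dimension = seq_along(f), f_score = f,
                             feature_added = sprintf("x%02d", seq_along(f))),
              class = c("acp_curve", "tbl_df", "tbl", "data.frame"),
              features = sprintf("x%02d", seq_along(f)))
  }
  up <- fake_curve(seq(0.1, 0.9, length.out = 25))
  expect_equal(attr(select_best(up), "dimension"), 25L)

  flat <- fake_curve(rep(0.8, 10))
  expect_equal(attr(select_best(flat), "dimension"), 1L)

  peak19 <- fake_curve(c(seq(0.3, 0.85, length.out = 19), rep(0.7, 11)))
  best <- select_best(peak19)
  expect_equal(attr(best, "dimension"), 19L)
  expect_equal(best$feature, sprintf("x%02d", 1:19))
})

test_that("knee_points extracts exactly the large-slope features", {
  f <- rep(0.1, 12)
  f[1] <- 0.25; f[4] <- 0.45; f[9] <- 0.65
  f <- cummax(f)  # step curve with jumps of ~0.2 at m in {1, 4, 9}
  curve <- structure(
    tibble::tibble(dimension = 1:12, f_score = f,
                   feature_added = sprintf("x%02d", 1:12)),
    class = c("acp_curve", "tbl_df", "tbl", "data.frame"),
    features = sprintf("x%02d", 1:12))
  kp <- knee_points(curve, min_gain = 0.1)
  expect_equal(kp$dimension, c(1L, 4L, 9L))
  expect_equal(kp$feature, c("x01", "x04", "x09"))

  # linear curve with per-step gain below the threshold: only the first
  # step (gain from the f(0) = 0 baseline) survives
  lin <- structure(
    tibble::tibble(dimension = 1:10,
                   f_score = seq(0.5, 0.59, by = 0.01),
                   feature_added = sprintf("l%02d", 1:10)),
    class = c("acp_curve", "tbl_df", "tbl", "data.frame"),
    features = sprintf("l%02d", 1:10))
  expect_equal(knee_points(lin, min_gain = 0.05)$dimension, 1L)

  # min_gain = 0 on a strictly increasing curve keeps every feature, and
  # knee set + complement = full ranking (nothing lost or duplicated)
  strict <- structure(
    tibble::tibble(dimension = 1:8, f_score = seq(0.1, 0.8, by = 0.1),
                   feature_added = sprintf("s%d", 1:8)),
    class = c("acp_curve", "tbl_df", "tbl", "data.frame"),
    features = sprintf("s%d", 1:8))
  kp0 <- knee_points(strict, min_gain = 0)
  expect_equal(kp0$feature, sprintf("s%d", 1:8))
})

test_that("greedy forward selection finds a perfectly separating feature and stops", {
  withr::with_seed(8, {
    y <- rep(c(0L, 1L), each = 20)
    data <- tibble::tibble(
      perfect = as.numeric(y) * 2 - 1 + rnorm(40, sd = 0.01),
      n1 = rnorm(40), n2 = rnorm(40), n3 = rnorm(40), n4 = rnorm(40),
      label = y)
  })
  g <- greedy_select(data, folds = 5, seed = 3)
  expect_equal(g$feature[1], "perfect")
  expect_lte(nrow(g), 2)  # no meaningful additions after the separator
  expect_equal(g$f_score[1], 1)

  g2 <- greedy_select(data, folds = 5, seed = 3)
  expect_identical(as.data.frame(g), as.data.frame(g2))
})

test_that("iterated reduction shrinks a noisy feature table onto the signal", {
  d <- simulate_peptides(n_pos = 40, n_neg = 40, bias = 2.5, seed = 10)
  feats <- add_noise_features(encode_aac(d), n_noise = 10, seed = 11)
  red <- iterate_reduction(feats, folds = 5, seed = 2, max_iter = 3)
  expect_lt(red$dimension, 30)
  expect_true(all(red$features %in% setdiff(names(feats), c("id", "label"))))
  expect_equal(red$history$iteration, seq_len(nrow(red$history)))
  # final curve belongs to the final ranking round
  expect_lte(red$dimension, nrow(red$curve))
  # slope points are a subset of the final selection curve's features
  expect_true(all(red$knee$feature %in% attr(red$curve, "features")))
})
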