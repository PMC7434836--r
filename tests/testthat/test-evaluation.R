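test_that("confusion counts follow the positive-class (anticancer) convention", {
  expect_equal(as.list(confusion(c(1, 1, 0, 0), c(1, 1, 0, 0))),
               list(tp = 2L, fp = 0L, tn = 2L, fn = 0L))
  expect_equal(as.list(confusion(c(1, 1, 0, 0), c(0, 0, 1, 1))),
               list(tp = 0L, fp = 2L, tn = 0L, fn = 2L))
  expect_equal(
    as.list(confusion(c(1, 1, 1, 1, 1, 0, 0, 0, 0, 0),
                      c(1, 1, 1, 0, 0, 1, 0, 0, 0, 0))),
    list(tp = 3L, fp = 1L, tn = 4L, fn = 2L))
  expect_error(confusion(c(1, 0), c(1, 0, 0)), "length")
  expect_error(confusion(c(1, 2), c(1, 0)), "binary")
})

test_that("metric arithmetic reproduces the hand-computed example exactly", {
  m <- metrics(tibble::tibble(tp = 3, fp = 1, tn = 4, fn = 2))
  expect_equal(m$sn, 0.6, tolerance = 1e-12)
  expect_equal(m$sp, 0.8, tolerance = 1e-12)
  expect_equal(m$acc, 0.7, tolerance = 1e-12)
  expect_equal(m$mcc, 10 / sqrt(600), tolerance = 1e-12)
  expect_equal(m$precision, 0.75, tolerance = 1e-12)
  expect_equal(m$recall, 0.6, tolerance = 1e-12)
  expect_equal(m$f_score, 2 * 0.75 * 0.6 / 1.35, tolerance = 1e-12)

  perfect <- metrics(tibble::tibble(tp = 10, fp = 0, tn = 10, fn = 0))
  expect_equal(perfect$acc, 1)
  expect_equal(perfect$mcc, 1)
  expect_equal(perfect$f_score, 1)
})

test_that("degenerate denominators: MCC = 0 and F = 0 conventions", {
  # all-negative prediction on balanced data
  allneg <- metrics(confusion(rep(c(1, 0), each = 5), rep(0, 10)))
  expect_equal(allneg$sn, 0)
  expect_equal(allneg$sp, 1)
  expect_equal(allneg$mcc, 0)
  expect_equal(allneg$f_score, 0)
  expect_error(metrics(tibble::tibble(tp = 0, fp = 0, tn = 0, fn = 0)), "empty")
})

test_that("metrics are scale-free and symmetric; weighted F tracks class support", {
  c1 <- tibble::tibble(tp = 3, fp = 1, tn = 4, fn = 2)
  c2 <- tibble::tibble(tp = 6, fp = 2, tn = 8, fn = 4)  # every sample doubled
  keep <- c("sn", "sp", "acc", "mcc", "f_score")
  expect_equal(metrics(c1)[keep], metrics(c2)[keep])

  # label+prediction swap: MCC and Acc invariant
  swapped <- tibble::tibble(tp = 4, fp = 2, tn = 3, fn = 1)
  expect_equal(metrics(swapped)$mcc, metrics(c1)$mcc)
  expect_equal(metrics(swapped)$acc, metrics(c1)$acc)

  mw <- metrics(c1, fscore = "weighted")
  f_pos <- 2 * 0.75 * 0.6 / 1.35
  f_neg <- 2 * (4 / 6) * (4 / 5) / (4 / 6 + 4 / 5)
  expect_equal(mw$f_score, (5 * f_pos + 5 * f_neg) / 10, tolerance = 1e-12)
})

test_that("pooled CV is reproducible, stratified, and auditable from counts", {
  d <- simulate_peptides(n_pos = 30, n_neg = 45, bias = 3, seed = 14)
  feats <- encode_aac(d)
  cv <- cross_validate(feats, folds = 5, seed = 9)
  cv2 <- cross_validate(feats, folds = 5, seed = 9)
  expect_identical(glance(cv), glance(cv2))
  expect_identical(cv$predictions, cv2$predictions)

  # every fold holds both classes and sizes are balanced within 1
  split_y <- split(d$label, cv$fold_assign)
  expect_true(all(vapply(split_y, function(y) length(unique(y)) == 2, TRUE)))
  expect_lte(diff(range(table(cv$fold_assign))), 2)

  # report recomputable from stored counts alone
  m <- cv$metrics
  expect_equal(metrics(m[c("tp", "fp", "tn", "fn")]), m)
  expect_equal(m$tp + m$fp + m$tn + m$fn, nrow(d))

  # per-fold diagnostics
  expect_equal(nrow(tidy(cv)), 5)
  expect_equal(sum(tidy(cv)$tp) + sum(tidy(cv)$fn), 30)

  # a strongly biased positive class is nearly separable
  expect_gte(m$acc, 0.9)

  expect_error(cross_validate(feats, folds = 40, seed = 1), "stratification")
  expect_error(cross_validate(dplyr::mutate(feats, label = 1L), folds = 2),
               "both classes")
})

test_that("SVM grid search returns the accuracy-maximizing corner deterministically", {
  d <- simulate_peptides(n_pos = 25, n_neg = 35, bias = 3, seed = 4)
  feats <- encode_gaac(d)

  single <- grid_search_svm(feats, c_grid = 2, g_grid = 0.5, folds = 5, seed = 2)
  expect_equal(single$best_c, 2)
  expect_equal(single$best_g, 0.5)
  expect_equal(nrow(tidy(single)), 1)

  # the published operating point is representable on the default grid
  c_grid <- 2^seq(-5, 15, by = 2)
  g_grid <- 2^seq(-15, 3, by = 2)
  expect_true(8192 %in% c_grid)
  expect_true(0.00048828125 %in% g_grid)

  small <- grid_search_svm(feats, c_grid = c(1, 32), g_grid = c(0.01, 0.25),
                           folds = 5, seed = 2)
  expect_equal(nrow(tidy(small)), 4)
  # selected point attains the maximum accuracy on the grid
  expect_equal(max(tidy(small)$acc), glance(small)$acc)
  small2 <- grid_search_svm(feats, c_grid = c(1, 32), g_grid = c(0.01, 0.25),
                            folds = 5, seed = 2)
  expect_identical(glance(small), glance(small2))
  expect_error(grid_search_svm(feats, c_grid = numeric(0)), "empty")
})

test_that("final models train, predict, refuse mismatched features, and round-trip", {
  # lengths >= 10 so every manifest feature (kmax 4, lambda 8) is computable
  d <- simulate_peptides(n_pos = 25, n_neg = 25, length_range = c(10, 30),
                         bias = 3, seed = 6)
  feats <- encode_aac(d)

  # separable set: large-cost SVM reaches training accuracy 1
  svm_fit <- train_final(feats, classifier_spec("svm_rbf", c = 1000), seed = 1)
  pred <- predict(svm_fit, feats)
  expect_equal(pred$label_pred, d$label)
  expect_true(all(pred$score[d$label == 1] > pred$score[d$label == 0] |
                    pred$label_pred == d$label))

  rf_fit <- train_final(feats, seed = 1)
  # peptide-table input: features are encoded from the model manifest
  pred_seq <- predict(rf_fit, d[3:5, c("id", "sequence")])
  pred_tab <- predict(rf_fit, feats[3:5, ])
  expect_equal(pred_seq, pred_tab)

  # serialization round trip: identical predictions on held-out data
  held <- simulate_peptides(n_pos = 10, n_neg = 10, bias = 3, seed = 99)
  bundle <- withr::local_tempfile(fileext = ".rds")
  save_model(rf_fit, bundle)
  reloaded <- load_model(bundle)
  expect_identical(predict(reloaded, encode_aac(held)),
                   predict(rf_fit, encode_aac(held)))

  # feature-count contract: a 7-feature model rejects a 20-column table
  m7 <- train_final(encode_selected(d, model_7d_manifest()), seed = 1)
  expect_error(predict(m7, feats), "feature mismatch")

  expect_equal(glance(rf_fit)$n_features, 20)
  expect_equal(nrow(tidy(rf_fit)), 20)
})

test_that("the majority-vote ensemble requires a strict majority for a positive call", {
  d <- simulate_peptides(n_pos = 20, n_neg = 20, bias = 3, seed = 13)
  feats <- encode_aac(d)
  spec <- classifier_spec("vote_ensemble")
  expect_equal(length(spec$members), 3)
  cv <- cross_validate(feats, spec, folds = 4, seed = 5)
  expect_gte(cv$metrics$acc, 0.8)
  cv2 <- cross_validate(feats, spec, folds = 4, seed = 5)
  expect_identical(cv$predictions, cv2$predictions)

  # two-member tie resolves to the negative class
  two <- classifier_spec("vote_ensemble", members = list(
    classifier_spec("random_forest", num_trees = 5),
    classifier_spec("svm_rbf", c = 0.01)))
  fit <- train_final(feats, two, seed = 1)
  votes <- vapply(fit$fit$fits, function(f)
    acpselect:::predict_classifier(f, as.matrix(feats[, 2:21]))$label,
    integer(nrow(feats)))
  tie_rows <- rowSums(votes) == 1
  if (any(tie_rows)) {
    expect_true(all(predict(fit, feats)$label_pred[tie_rows] == 0L))
  }
})

test_that("null calibration: shuffled labels give majority-rate accuracy", {
  d <- simulate_peptides(n_pos = 30, n_neg = 30, bias = 3, seed = 20)
  feats <- encode_aac(d)
  accs <- vapply(1:8, function(s) {
    shuffled <- dplyr::mutate(feats,
                              label = withr::with_seed(100 + s, sample(label)))
    cross_validate(shuffled, folds = 5, seed = s)$metrics$acc
  }, numeric(1))
  se <- sd(accs) / sqrt(length(accs))
  expect_lt(abs(mean(accs) - 0.5), 3 * max(se, 0.02))
})
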