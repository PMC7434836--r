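#' Confusion counts for binary peptide classification
#'
#' Tallies a prediction against truth with the anticancer class (label 1) as
#' positive: TP = anticancer peptides predicted anticancer, FP =
#' non-anticancer predicted anticancer, TN = non-anticancer predicted
#' non-anticancer, FN = anticancer predicted non-anticancer.
#'
#' @param y_true,y_pred Equal-length binary (0/1) vectors.
#' @return A one-row tibble with integer columns `tp`, `fp`, `tn`, `fn`.
#' @examples
#' confusion(c(1, 1, 0, 0), c(1, 1, 0, 0))
#' @export
confusion <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) {
    stop("y_true and y_pred have different lengths", call. = FALSE)
  }
  y_true <- as.integer(y_true); y_pred <- as.integer(y_pred)
  if (!all(y_true %in% c(0L, 1L)) || !all(y_pred %in% c(0L, 1L))) {
    stop("labels must be binary 0/1", call. = FALSE)
  }
  tibble::tibble(
    tp = sum(y_true == 1L & y_pred == 1L),
    fp = sum(y_true == 0L & y_pred == 1L),
    tn = sum(y_true == 0L & y_pred == 0L),
    fn = sum(y_true == 1L & y_pred == 0L)
  )
}

#' Classification metrics from confusion counts
#'
#' Computes sensitivity `Sn = TP/(TP+FN)`, specificity `Sp = TN/(TN+FP)`,
#' accuracy `Acc = (TP+TN)/(TP+TN+FP+FN)`, the Matthews correlation
#' coefficient `MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`,
#' precision `P = TP/(TP+FP)`, recall `R = Sn` and the F-score
#' `2*P*R/(P+R)`. Degenerate denominators follow the conventions required
#' for metrics to be total over weak feature subsets: a zero MCC denominator
#' gives MCC = 0, `P + R = 0` gives F-score = 0, and an empty class gives
#' Sn (or Sp, or P) = 0.
#'
#' @param counts A one-row data frame with columns `tp`, `fp`, `tn`, `fn`
#'   (as from [confusion()]), totalling at least 1.
#' @param fscore `"positive"` (default): F1 of the anticancer class;
#'   `"weighted"`: support-weighted mean of the per-class F1 scores.
#' @return A one-row tibble with columns `sn`, `sp`, `acc`, `mcc`,
#'   `f_score`, `precision`, `recall`, `tp`, `fp`, `tn`, `fn` — every
#'   metric recomputable from the count columns alone.
#' @examples
#' metrics(confusion(c(1,1,1,1,1,0,0,0,0,0), c(1,1,1,0,0,1,0,0,0,0)))
#' @export
metrics <- function(counts, fscore = c("positive", "weighted")) {
  fscore <- match.arg(fscore)
  stopifnot(all(c("tp", "fp", "tn", "fn") %in% names(counts)))
  tp <- as.numeric(counts$tp[1]); fp <- as.numeric(counts$fp[1])
  tn <- as.numeric(counts$tn[1]); fn <- as.numeric(counts$fn[1])
  total <- tp + fp + tn + fn
  if (total < 1) stop("empty confusion counts", call. = FALSE)
  safe_div <- function(num, den) if (den == 0) 0 else num / den
  sn <- safe_div(tp, tp + fn)
  sp <- safe_div(tn, tn + fp)
  acc <- (tp + tn) / total
  mcc_den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (mcc_den == 0) 0 else (tp * tn - fp * fn) / sqrt(mcc_den)
  prec <- safe_div(tp, tp + fp)
  rec <- sn
  f_pos <- safe_div(2 * prec * rec, prec + rec)
  f <- if (fscore == "positive") f_pos else {
    prec_n <- safe_div(tn, tn + fn)
    rec_n <- safe_div(tn, tn + fp)
    f_neg <- safe_div(2 * prec_n * rec_n, prec_n + rec_n)
    ((tp + fn) * f_pos + (tn + fp) * f_neg) / total
  }
  tibble::tibble(sn = sn, sp = sp, acc = acc, mcc = mcc, f_score = f,
                 precision = prec, recall = rec,
                 tp = as.integer(tp), fp = as.integer(fp),
                 tn = as.integer(tn), fn = as.integer(fn))
}

#' Classifier specifications
#'
#' A serializable description of a classifier; a spec plus a seed plus data
#' fully determines the fitted model and its predictions.
#'
#' * `"random_forest"`: a seeded probability forest
#'   ([ranger::ranger()]), `num_trees` trees (default 100), single thread,
#'   raw (unstandardized) features.
#' * `"svm_rbf"`: an RBF-kernel support vector machine via the libSVM
#'   binding ([e1071::svm()]) with cost `c` and kernel width `g`; features
#'   are standardized to training-fold mean 0 / sd 1 before fitting.
#' * `"vote_ensemble"`: a plain majority vote over a list of member specs;
#'   a tie (possible with an even member count) is resolved to the negative
#'   class, i.e. a strict majority is required to call a peptide
#'   anticancer.
#'
#' @param kind One of `"random_forest"`, `"svm_rbf"`, `"vote_ensemble"`.
#' @param c,g SVM cost and RBF gamma (defaults 1 and `1/d` at fit time when
#'   `g = NULL`).
#' @param num_trees Number of trees for the forest (default 100).
#' @param members For `"vote_ensemble"`: list of member specs (default: a
#'   forest plus an SVM plus a 500-tree forest).
#' @return An object of class `acp_classifier_spec`.
#' @examples
#' classifier_spec("svm_rbf", c = 8192, g = 0.00048828125)
#' @export
classifier_spec <- function(kind = c("random_forest", "svm_rbf", "vote_ensemble"),
                            c = 1, g = NULL, num_trees = 100L,
                            members = NULL) {
  kind <- match.arg(kind)
  if (kind == "vote_ensemble" && is.null(members)) {
    members <- list(classifier_spec("random_forest"),
                    classifier_spec("svm_rbf"),
                    classifier_spec("random_forest", num_trees = 500L))
  }
  if (!is.null(c) && c <= 0) stop("SVM cost c must be positive", call. = FALSE)
  if (!is.null(g) && g <= 0) stop("SVM gamma g must be positive", call. = FALSE)
  if (num_trees < 1) stop("num_trees must be >= 1", call. = FALSE)
  structure(list(kind = kind, c = c, g = g, num_trees = as.integer(num_trees),
                 members = members),
            class = "acp_classifier_spec")
}

#' @export
print.acp_classifier_spec <- function(x, ...) {
  cat("<acp_classifier_spec>", x$kind, "\n")
  if (x$kind == "svm_rbf") {
    cat("  c =", x$c, " g =", if (is.null(x$g)) "1/d" else x$g, "\n")
  }
  if (x$kind == "random_forest") cat("  num_trees =", x$num_trees, "\n")
  if (x$kind == "vote_ensemble") cat("  members =", length(x$members), "\n")
  invisible(x)
}

## ---- internal fitting -----------------------------------------------------

## X: numeric matrix; y: integer 0/1. Returns a fit object with a predict
## closure-free structure (everything serializable via saveRDS).
fit_classifier <- function(X, y, spec, seed) {
  stopifnot(inherits(spec, "acp_classifier_spec"))
  ## canonical column order: fitted models (and hence CV metrics) are
  ## invariant to the order feature columns arrive in
  X <- X[, sort(colnames(X)), drop = FALSE]
  switch(spec$kind,
    random_forest = {
      fit <- ranger::ranger(x = as.data.frame(X),
                            y = factor(y, levels = c(0L, 1L)),
                            num.trees = spec$num_trees,
                            probability = TRUE, seed = seed,
                            num.threads = 1L, verbose = FALSE)
      list(kind = "random_forest", fit = fit, features = colnames(X))
    },
    svm_rbf = {
      mu <- colMeans(X)
      sd_ <- apply(X, 2, stats::sd)
      sd_[sd_ == 0] <- 1
      Z <- sweep(sweep(X, 2, mu), 2, sd_, "/")
      g <- if (is.null(spec$g)) 1 / ncol(X) else spec$g
      fit <- e1071::svm(Z, factor(y, levels = c(0L, 1L)), type = "C-classification",
                        kernel = "radial", cost = spec$c, gamma = g,
                        scale = FALSE)
      list(kind = "svm_rbf", fit = fit, mu = mu, sd = sd_,
           features = colnames(X))
    },
    vote_ensemble = {
      fits <- lapply(seq_along(spec$members), function(i)
        fit_classifier(X, y, spec$members[[i]], seed + i))
      list(kind = "vote_ensemble", fits = fits, features = colnames(X),
           majority = as.integer(mean(y) > 0.5))
    }
  )
}

predict_classifier <- function(model, X) {
  X <- X[, model$features, drop = FALSE]
  switch(model$kind,
    random_forest = {
      pr <- stats::predict(model$fit, data = as.data.frame(X),
                           num.threads = 1L, verbose = FALSE)$predictions
      score <- pr[, "1"]
      list(label = as.integer(score > 0.5), score = as.numeric(score))
    },
    svm_rbf = {
      Z <- sweep(sweep(X, 2, model$mu), 2, model$sd, "/")
      pred <- stats::predict(model$fit, Z, decision.values = TRUE)
      dv <- attr(pred, "decision.values")
      ## e1071 names the column "a/b": positive values favor class a.
      ## Orient the score so larger = more anticancer-like (class 1).
      sign_ <- if (identical(colnames(dv)[1], "1/0")) 1 else -1
      list(label = as.integer(as.character(pred)),
           score = sign_ * as.numeric(dv[, 1]))
    },
    vote_ensemble = {
      votes <- vapply(model$fits, function(f) predict_classifier(f, X)$label,
                      integer(nrow(X)))
      votes <- matrix(votes, nrow = nrow(X))
      share <- rowMeans(votes)
      list(label = as.integer(share > 0.5), score = share)
    }
  )
}

## ---- cross-validation -----------------------------------------------------

## Seeded stratified fold assignment: within each class, indices are
## shuffled and dealt round-robin, so every fold holds both classes whenever
## min(class size) >= folds.
stratified_folds <- function(y, folds, seed) {
  if (length(y) < folds) stop("fewer samples than folds", call. = FALSE)
  if (min(table(factor(y, levels = c(0, 1)))) < folds) {
    stop("stratification impossible: a class has fewer members than folds",
         call. = FALSE)
  }
  assign <- integer(length(y))
  withr::with_seed(seed, {
    for (cls in c(0L, 1L)) {
      idx <- sample(which(y == cls))
      assign[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  assign
}

split_features_labels <- function(data, label_col = "label") {
  stopifnot(is.data.frame(data), label_col %in% names(data))
  y <- as.integer(data[[label_col]])
  if (!all(y %in% c(0L, 1L))) stop("labels must be binary 0/1", call. = FALSE)
  drop <- c("id", label_col)
  X <- as.matrix(data[, setdiff(names(data), drop), drop = FALSE])
  storage.mode(X) <- "double"
  list(X = X, y = y, ids = if ("id" %in% names(data)) data$id else NULL)
}

## cv with precomputed fold assignment; pooled protocol
cv_with_folds <- function(X, y, spec, fold_assign, seed, fscore = "positive") {
  folds <- max(fold_assign)
  pred <- integer(length(y))
  score <- numeric(length(y))
  per_fold <- vector("list", folds)
  for (f in seq_len(folds)) {
    te <- fold_assign == f
    model <- fit_classifier(X[!te, , drop = FALSE], y[!te], spec,
                            seed = seed + f)
    p <- predict_classifier(model, X[te, , drop = FALSE])
    pred[te] <- p$label
    score[te] <- p$score
    per_fold[[f]] <- dplyr::mutate(
      metrics(confusion(y[te], p$label), fscore = fscore), fold = f,
      .before = 1)
  }
  pooled <- metrics(confusion(y, pred), fscore = fscore)
  structure(list(metrics = pooled, per_fold = dplyr::bind_rows(per_fold),
                 fold_assign = fold_assign, predictions = pred,
                 scores = score, spec = spec, seed = seed, folds = folds,
                 fscore = fscore),
            class = "acp_cv")
}

#' Stratified cross-validation with pooled metrics
#'
#' Splits the data into seeded stratified folds (within each class, a seeded
#' shuffle dealt round-robin), fits the classifier on each training split,
#' and pools the out-of-fold predictions into a single confusion table from
#' which the five metrics (Sn, Sp, Acc, MCC, F-score) are computed once —
#' the pooled protocol that yields single headline numbers. Per-fold metrics
#' are kept for diagnostics ([tidy()]); the pooled row is available via
#' [glance()].
#'
#' @param data A feature tibble: optional `id` column, numeric feature
#'   columns, and a binary label column.
#' @param spec An [classifier_spec()] (default: 100-tree random forest).
#' @param folds Number of folds (default 10); each class must have at least
#'   `folds` members.
#' @param seed Integer seed controlling fold assignment and the forest;
#'   identical calls with identical seeds are bit-identical.
#' @param label_col Name of the label column (default `"label"`).
#' @param fscore F-score convention, see [metrics()].
#' @return An object of class `acp_cv` with elements `metrics` (pooled
#'   one-row tibble), `per_fold`, `fold_assign`, `predictions`, `scores`,
#'   `spec`, `seed`.
#' @examples
#' set.seed(1)
#' d <- simulate_peptides(n_pos = 30, n_neg = 30, bias = 3, seed = 7)
#' cv <- encode_aac(d) |> cross_validate(folds = 5, seed = 1)
#' glance(cv)
#' @export
cross_validate <- function(data, spec = classifier_spec("random_forest"),
                           folds = 10L, seed = 1L, label_col = "label",
                           fscore = c("positive", "weighted")) {
  fscore <- match.arg(fscore)
  if (folds < 2) stop("folds must be >= 2", call. = FALSE)
  parts <- split_features_labels(data, label_col)
  if (length(unique(parts$y)) < 2) {
    stop("both classes must be present", call. = FALSE)
  }
  fold_assign <- stratified_folds(parts$y, folds, seed)
  cv_with_folds(parts$X, parts$y, spec, fold_assign, seed, fscore)
}

#' @export
print.acp_cv <- function(x, ...) {
  cat("<acp_cv> ", x$spec$kind, ", ", x$folds, "-fold, seed ", x$seed,
      "\n", sep = "")
  print(x$metrics)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname cross_validate
#' @param x An `acp_cv` object.
#' @param ... Unused.
#' @export
tidy.acp_cv <- function(x, ...) x$per_fold

#' @rdname cross_validate
#' @export
glance.acp_cv <- function(x, ...) {
  dplyr::mutate(x$metrics, folds = x$folds, seed = x$seed,
                classifier = x$spec$kind)
}

#' Grid search for the RBF-SVM cost and kernel width
#'
#' Exhaustive seeded cross-validated search over a (c, g) grid for the
#' RBF-kernel SVM, maximizing pooled CV accuracy. Ties are broken toward the
#' smaller `c`, then the smaller `g`. The default grids are the customary
#' powers of two, `c` in 2^-5..2^15 and `g` in 2^-15..2^3 (step 2^2).
#'
#' @inheritParams cross_validate
#' @param c_grid,g_grid Numeric vectors of candidate values.
#' @return An object of class `acp_grid`: `best_c`, `best_g`, `metrics`
#'   (pooled report at the optimum) and `results` (one row per grid point;
#'   also via [tidy()]).
#' @export
grid_search_svm <- function(data, c_grid = 2^seq(-5, 15, by = 2),
                            g_grid = 2^seq(-15, 3, by = 2), folds = 10L,
                            seed = 1L, label_col = "label",
                            fscore = c("positive", "weighted")) {
  fscore <- match.arg(fscore)
  if (!length(c_grid) || !length(g_grid)) {
    stop("empty hyperparameter grid", call. = FALSE)
  }
  parts <- split_features_labels(data, label_col)
  fold_assign <- stratified_folds(parts$y, folds, seed)
  grid <- tidyr::expand_grid(c = sort(c_grid), g = sort(g_grid))
  res <- purrr::pmap(grid, function(c, g) {
    cv <- cv_with_folds(parts$X, parts$y, classifier_spec("svm_rbf", c = c, g = g),
                        fold_assign, seed, fscore)
    dplyr::mutate(cv$metrics, c = c, g = g, .before = 1)
  })
  results <- dplyr::bind_rows(res)
  best <- dplyr::arrange(results, dplyr::desc(.data$acc), .data$c, .data$g)[1, ]
  structure(list(best_c = best$c, best_g = best$g,
                 metrics = dplyr::select(best, -dplyr::all_of(c("c", "g"))),
                 results = results, folds = folds, seed = seed),
            class = "acp_grid")
}

#' @export
print.acp_grid <- function(x, ...) {
  cat("<acp_grid> best c =", x$best_c, ", g =", x$best_g, "\n")
  print(x$metrics)
  invisible(x)
}

#' @rdname grid_search_svm
#' @param x An `acp_grid` object.
#' @param ... Unused.
#' @export
tidy.acp_grid <- function(x, ...) x$results

#' @rdname grid_search_svm
#' @export
glance.acp_grid <- function(x, ...) {
  dplyr::mutate(x$metrics, c = x$best_c, g = x$best_g,
                folds = x$folds, seed = x$seed)
}

#' Train a final model on all data
#'
#' Fits the classifier on the full dataset and bundles it with everything a
#' later prediction needs: the ordered feature manifest, the spec, the seed
#' and (for the SVM) the standardization parameters. The bundle survives a
#' [save_model()] / [load_model()] round trip with bit-identical
#' predictions, and refuses feature tables whose columns do not match its
#' manifest. When given a peptide table (with a `sequence` column),
#' [predict.acp_model()] encodes the manifest features itself via
#' [encode_selected()].
#'
#' @inheritParams cross_validate
#' @return An object of class `acp_model`.
#' @examples
#' d <- simulate_peptides(n_pos = 25, n_neg = 25, bias = 3, seed = 2)
#' m <- encode_aac(d) |> train_final(seed = 1)
#' predict(m, d[1:3, ])
#' @export
train_final <- function(data, spec = classifier_spec("random_forest"),
                        seed = 1L, label_col = "label") {
  parts <- split_features_labels(data, label_col)
  if (length(unique(parts$y)) < 2) {
    stop("both classes must be present", call. = FALSE)
  }
  fit <- fit_classifier(parts$X, parts$y, spec, seed)
  structure(list(fit = fit, features = colnames(parts$X), spec = spec,
                 seed = seed, n = nrow(parts$X),
                 class_balance = mean(parts$y)),
            class = "acp_model")
}

#' @rdname train_final
#' @param object An `acp_model`.
#' @param newdata A feature tibble with exactly the model's feature columns,
#'   or a peptide tibble with a `sequence` column (features are then encoded
#'   from the model's manifest).
#' @param ... Unused.
#' @return `predict()`: a tibble `id`, `label_pred` (0/1), `score` (larger =
#'   more anticancer-like).
#' @export
predict.acp_model <- function(object, newdata, ...) {
  stopifnot(is.data.frame(newdata))
  if ("sequence" %in% names(newdata)) {
    newdata <- encode_selected(newdata, object$features)
  }
  ids <- if ("id" %in% names(newdata)) newdata$id
         else sprintf("row%d", seq_len(nrow(newdata)))
  cols <- setdiff(names(newdata), c("id", "label"))
  if (!identical(sort(cols), sort(object$features))) {
    stop("feature mismatch: model expects ", length(object$features),
         " feature(s) [", paste(utils::head(object$features, 3), collapse = ", "),
         ", ...], got ", length(cols), call. = FALSE)
  }
  X <- as.matrix(newdata[, object$features, drop = FALSE])
  storage.mode(X) <- "double"
  p <- predict_classifier(object$fit, X)
  tibble::tibble(id = ids, label_pred = p$label, score = p$score)
}

#' @export
print.acp_model <- function(x, ...) {
  cat("<acp_model> ", x$spec$kind, ", ", length(x$features),
      " feature(s), trained on n = ", x$n, "\n", sep = "")
  invisible(x)
}

#' @rdname train_final
#' @param x An `acp_model`.
#' @export
tidy.acp_model <- function(x, ...) {
  tibble::tibble(feature = x$features,
                 position = seq_along(x$features))
}

#' @rdname train_final
#' @export
glance.acp_model <- function(x, ...) {
  tibble::tibble(classifier = x$spec$kind, n_features = length(x$features),
                 n = x$n, positive_fraction = x$class_balance, seed = x$seed)
}

#' Save and load a model bundle
#'
#' Serializes an [train_final()] bundle (model + feature manifest +
#' standardization parameters + spec + seed) to a single file.
#'
#' @param model An `acp_model`.
#' @param path File path for the bundle.
#' @return `save_model()`: `path` invisibly; `load_model()`: the
#'   `acp_model`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "acp_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "acp_model")) {
    stop("file does not contain an acp_model bundle", call. = FALSE)
  }
  model
}
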