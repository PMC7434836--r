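#' Max-relevance-max-distance feature ranking
#'
#' Scores every feature with the MRMD-style composite
#' `score = relevance + distance`: the relevance of feature `i` is the
#' absolute Pearson correlation of its values with the binary label (for a
#' 0/1 label this equals the point-biserial correlation), and the distance
#' component is the mean Euclidean distance between feature `i` and every
#' other feature after each feature column has been standardized (z-scored,
#' then scaled to unit norm, so the pairwise distance is
#' `sqrt(2 * (1 - r_ij))` and lives on the same `[0, 2]` scale as the
#' relevance term). Highly label-correlated features score high on
#' relevance; features redundant with many others score low on distance.
#' Features are returned sorted by descending score, ties broken by feature
#' name — deterministic across runs and platforms.
#'
#' A zero-variance feature has relevance 0 by convention (not an error) and
#' a zero vector after standardization.
#'
#' Alternative scorers can be plugged in: `relevance = "anova_f"` maps the
#' one-way ANOVA F statistic to the correlation scale
#' `sqrt(F / (F + n - 2))`; `distance = "cosine"` uses `1 - cos` similarity
#' of the standardized columns and `"tanimoto"` the continuous Tanimoto
#' dissimilarity. The scorers used are recorded on the result.
#'
#' @param data A feature tibble: optional `id`, numeric feature columns, and
#'   a binary label column. At least 4 rows and both classes required.
#' @param label_col Name of the label column (default `"label"`).
#' @param relevance One of `"pearson"` (default), `"point_biserial"`
#'   (identical for binary labels), `"anova_f"`.
#' @param distance One of `"euclidean"` (default), `"cosine"`,
#'   `"tanimoto"`.
#' @return A tibble with class `acp_ranking`: columns `rank`, `feature`,
#'   `relevance`, `distance`, `score` (non-increasing); a permutation of the
#'   input feature set. The scorers are stored in attributes `relevance` and
#'   `distance`.
#' @examples
#' d <- simulate_peptides(n_pos = 40, n_neg = 60, bias = 2, seed = 3)
#' encode_aac(d) |> rank_features() |> head()
#' @export
rank_features <- function(data, label_col = "label",
                          relevance = c("pearson", "point_biserial", "anova_f"),
                          distance = c("euclidean", "cosine", "tanimoto")) {
  relevance <- match.arg(relevance)
  distance <- match.arg(distance)
  parts <- split_features_labels(data, label_col)
  X <- parts$X; y <- parts$y
  n <- nrow(X); d <- ncol(X)
  if (n < 4) stop("need at least 4 samples to rank features", call. = FALSE)
  if (d < 1) stop("no feature columns", call. = FALSE)
  if (length(unique(y)) < 2) stop("both classes must be present", call. = FALSE)

  sds <- apply(X, 2, stats::sd)
  rel <- vapply(seq_len(d), function(j) {
    if (sds[j] == 0) return(0)
    r <- abs(stats::cor(X[, j], y))
    if (relevance == "anova_f") {
      f <- r^2 / (1 - r^2) * (n - 2)
      if (!is.finite(f)) 1 else sqrt(f / (f + n - 2))
    } else r
  }, numeric(1))

  ## standardized unit-norm columns; zero-variance columns stay zero
  Z <- scale(X)
  Z[, sds == 0] <- 0
  nrm <- sqrt(colSums(Z^2))
  U <- sweep(Z, 2, pmax(nrm, .Machine$double.eps), "/")
  G <- crossprod(U)
  norms <- diag(G)
  dist_comp <- vapply(seq_len(d), function(j) {
    if (d == 1) return(0)
    others <- setdiff(seq_len(d), j)
    dd <- switch(distance,
      euclidean = sqrt(pmax(norms[j] + norms[others] - 2 * G[j, others], 0)),
      cosine = 1 - G[j, others] / pmax(sqrt(norms[j] * norms[others]), 1e-300),
      tanimoto = 1 - G[j, others] /
        pmax(norms[j] + norms[others] - G[j, others], 1e-300))
    mean(dd)
  }, numeric(1))

  out <- tibble::tibble(feature = colnames(X), relevance = rel,
                        distance = dist_comp, score = rel + dist_comp)
  out <- dplyr::arrange(out, dplyr::desc(.data$score), .data$feature)
  out <- dplyr::mutate(out, rank = dplyr::row_number(), .before = 1)
  structure(out, class = c("acp_ranking", class(out)),
            relevance = relevance, distance = distance)
}

#' Incremental top-m cross-validation curve
#'
#' The rank-then-incrementally-evaluate procedure: the highest-ranked
#' feature is evaluated alone by stratified cross-validation, the
#' second-ranked feature is added and the pair re-evaluated, and so on until
#' the full feature set has been examined. The result — one metric report
#' per dimension — is the data behind the F-score-versus-dimension line
#' charts from which low-dimensional subsets are read off with
#' [select_best()] and [knee_points()].
#'
#' The fold assignment is fixed once from the seed, so the point at `m = d`
#' equals a direct [cross_validate()] call on the full matrix with the same
#' seed, and the whole curve is bit-identical under a fixed seed.
#'
#' @inheritParams cross_validate
#' @param ranking An `acp_ranking` from [rank_features()] (computed from
#'   `data` if omitted).
#' @return A tibble with class `acp_curve`: columns `dimension`,
#'   `feature_added`, `sn`, `sp`, `acc`, `mcc`, `f_score`, `precision`,
#'   `recall`, `tp`, `fp`, `tn`, `fn` — one row per dimension 1..d, strictly
#'   increasing. Classifier kind, folds and seed are stored as attributes.
#' @examples
#' d <- simulate_peptides(n_pos = 30, n_neg = 30, bias = 2, seed = 5)
#' feats <- encode_gaac(d)
#' curve <- incremental_curve(feats, folds = 5, seed = 1)
#' curve[, c("dimension", "feature_added", "f_score")]
#' @export
incremental_curve <- function(data, ranking = NULL,
                              spec = classifier_spec("random_forest"),
                              folds = 10L, seed = 1L, label_col = "label",
                              fscore = c("positive", "weighted")) {
  fscore <- match.arg(fscore)
  if (is.null(ranking)) ranking <- rank_features(data, label_col = label_col)
  stopifnot(is.data.frame(ranking), "feature" %in% names(ranking))
  parts <- split_features_labels(data, label_col)
  feats <- ranking$feature
  if (!all(feats %in% colnames(parts$X))) {
    stop("ranking names feature(s) absent from the data", call. = FALSE)
  }
  fold_assign <- stratified_folds(parts$y, folds, seed)
  rows <- lapply(seq_along(feats), function(m) {
    cv <- cv_with_folds(parts$X[, feats[seq_len(m)], drop = FALSE], parts$y,
                        spec, fold_assign, seed, fscore)
    dplyr::mutate(cv$metrics, dimension = m, feature_added = feats[m],
                  .before = 1)
  })
  out <- dplyr::bind_rows(rows)
  structure(out, class = c("acp_curve", class(out)),
            classifier = spec$kind, folds = folds, seed = seed,
            features = feats)
}

curve_features <- function(curve) attr(curve, "features", exact = TRUE) %||%
  curve$feature_added

#' Best dimension on a selection curve
#'
#' Returns the smallest dimension `m` maximizing the F-score on an
#' incremental curve (ties resolved to the smaller dimension), together with
#' the corresponding top-`m` features.
#'
#' @param curve An `acp_curve` from [incremental_curve()].
#' @return A tibble of the selected features (columns `rank`, `feature`)
#'   with attributes `dimension` and `f_score`.
#' @export
select_best <- function(curve) {
  stopifnot(is.data.frame(curve), nrow(curve) >= 1,
            all(c("dimension", "f_score") %in% names(curve)))
  m <- curve$dimension[which.max(curve$f_score)]  # which.max: first maximum
  feats <- curve_features(curve)[seq_len(m)]
  structure(tibble::tibble(rank = seq_len(m), feature = feats),
            dimension = m, f_score = max(curve$f_score))
}

#' Slope-point ("knee") features of a selection curve
#'
#' Extracts the features whose addition produced a large jump in the
#' incremental F-score curve: all dimensions `m` with
#' `f_score(m) - f_score(m-1) > min_gain`, where `f_score(0)` is defined as
#' 0. These slope points are how the final low-dimensional (e.g.
#' seven-feature) model is separated from the last reduced-dimension curve.
#'
#' @param curve An `acp_curve`.
#' @param min_gain Minimum F-score gain for a feature to count as a slope
#'   point (default 0.01 absolute; the threshold is reported on the result).
#' @return A tibble with columns `dimension`, `feature`, `gain`; attribute
#'   `min_gain`.
#' @export
knee_points <- function(curve, min_gain = 0.01) {
  stopifnot(is.data.frame(curve), nrow(curve) >= 1, min_gain >= 0)
  f <- curve$f_score
  gain <- diff(c(0, f))
  keep <- which(gain > min_gain)
  structure(tibble::tibble(dimension = curve$dimension[keep],
                           feature = curve_features(curve)[keep],
                           gain = gain[keep]),
            min_gain = min_gain)
}

#' Greedy forward feature selection
#'
#' Sequential forward selection: starting from the empty set, repeatedly add
#' the feature whose addition maximizes the pooled cross-validated F-score
#' (ties broken by feature name), stopping when no addition improves it.
#'
#' @inheritParams cross_validate
#' @param max_features Optional cap on the subset size.
#' @return A tibble with class `acp_greedy`: one row per accepted feature
#'   (columns `step`, `feature`, `f_score`); the selected subset in
#'   acceptance order.
#' @export
greedy_select <- function(data, spec = classifier_spec("random_forest"),
                          folds = 10L, seed = 1L, label_col = "label",
                          fscore = c("positive", "weighted"),
                          max_features = Inf) {
  fscore <- match.arg(fscore)
  parts <- split_features_labels(data, label_col)
  fold_assign <- stratified_folds(parts$y, folds, seed)
  remaining <- sort(colnames(parts$X))
  chosen <- character(0)
  best_f <- -Inf
  trace <- list()
  while (length(remaining) && length(chosen) < max_features) {
    scores <- vapply(remaining, function(f) {
      cv <- cv_with_folds(parts$X[, c(chosen, f), drop = FALSE], parts$y,
                          spec, fold_assign, seed, fscore)
      cv$metrics$f_score
    }, numeric(1))
    cand <- remaining[which.max(scores)]  # remaining is sorted: name tie-break
    if (max(scores) <= best_f) break
    best_f <- max(scores)
    chosen <- c(chosen, cand)
    remaining <- setdiff(remaining, cand)
    trace[[length(trace) + 1]] <- tibble::tibble(
      step = length(chosen), feature = cand, f_score = best_f)
  }
  structure(dplyr::bind_rows(trace),
            class = c("acp_greedy", "tbl_df", "tbl", "data.frame"),
            folds = folds, seed = seed, classifier = spec$kind)
}

#' Iterated dimension reduction
#'
#' Repeats the rank / incremental-curve / best-subset cycle on the surviving
#' features until the selected dimension stops shrinking or `max_iter`
#' rounds have run — the loop that turns a merged high-dimensional feature
#' table into a compact model (the route by which a 19-feature model and,
#' from its final curve's slope points, a 7-feature model are obtained).
#'
#' @inheritParams incremental_curve
#' @param max_iter Maximum reduction rounds (default 10).
#' @param min_gain Slope-point threshold recorded for the final curve.
#' @return A list of class `acp_reduction`: `features` (final subset, in
#'   final-ranking order), `dimension`, `curve` (final `acp_curve`),
#'   `knee` (slope points of the final curve), `history` (tibble of
#'   per-round dimensions and F-scores).
#' @export
iterate_reduction <- function(data, spec = classifier_spec("random_forest"),
                              folds = 10L, seed = 1L, label_col = "label",
                              fscore = c("positive", "weighted"),
                              max_iter = 10L, min_gain = 0.01) {
  fscore <- match.arg(fscore)
  current <- setdiff(names(data), c("id", label_col))
  history <- list()
  curve <- NULL
  for (iter in seq_len(max_iter)) {
    sub <- data[, c(intersect(names(data), "id"), current, label_col)]
    ranking <- rank_features(sub, label_col = label_col)
    curve <- incremental_curve(sub, ranking, spec = spec, folds = folds,
                               seed = seed, label_col = label_col,
                               fscore = fscore)
    best <- select_best(curve)
    history[[iter]] <- tibble::tibble(
      iteration = iter, dimension_in = length(current),
      dimension_out = attr(best, "dimension"),
      f_score = attr(best, "f_score"))
    new <- best$feature
    if (length(new) >= length(current)) { current <- new; break }
    current <- new
  }
  structure(list(features = current, dimension = length(current),
                 curve = curve, knee = knee_points(curve, min_gain),
                 history = dplyr::bind_rows(history)),
            class = "acp_reduction")
}

#' @export
print.acp_reduction <- function(x, ...) {
  cat("<acp_reduction> ", nrow(x$history), " round(s) -> ", x$dimension,
      " feature(s)\n", sep = "")
  print(x$history)
  invisible(x)
}
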