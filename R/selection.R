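# Three-stage feature selection: a per-feature Welch t-test filter (no
# multiplicity correction), a univariate AUC ranking, and recursive
# elimination of the lowest-ranked feature with cross-validated DPGMM
# classification performance recorded at each step.

#' Welch t-test filter
#'
#' Each feature is tested for a location difference between the positive
#' and negative class (Welch two-sample t-test).  Features with p-value
#' above `alpha` are removed; no multiple-testing correction is applied at
#' this stage.  Features with zero variance in both classes have an
#' undefined statistic and are removed as degenerate.
#'
#' @param features Feature tibble (see [build_feature_matrix()]) with a
#'   `label` metadata column, or a numeric matrix plus `labels`.
#' @param labels Optional label vector when `features` is a matrix.
#' @param alpha Retention threshold on the p-value (default 0.05).
#' @return A list with `retained` (feature names), `removed` (tibble of
#'   `feature`, `p_value`, `reason`) and `p_values` (tibble for all
#'   features).
#' @export
ttest_filter <- function(features, labels = NULL, alpha = 0.05) {
  if (is.data.frame(features)) {
    parts <- feature_parts(features)
    x <- parts$x
    labels <- parts$meta$label
  } else {
    x <- as.matrix(features)
  }
  pos <- labels == "positive"
  neg <- labels == "negative"
  if (sum(pos) < 2L || sum(neg) < 2L) {
    stop("both classes need at least 2 samples", call. = FALSE)
  }
  fn <- colnames(x)
  pv <- vapply(seq_len(ncol(x)), function(j) {
    a <- x[pos, j]
    b <- x[neg, j]
    if (stats::sd(a) == 0 && stats::sd(b) == 0) return(NA_real_)
    stats::t.test(a, b)$p.value
  }, numeric(1))
  p_values <- tibble::tibble(feature = fn, p_value = pv)
  degenerate <- is.na(pv)
  dropped <- degenerate | pv > alpha
  removed <- tibble::tibble(
    feature = fn[dropped],
    p_value = pv[dropped],
    reason = ifelse(degenerate[dropped], "zero_variance", "non_discriminative")
  )
  list(retained = fn[!dropped], removed = removed, p_values = p_values)
}

#' Univariate AUC ranking
#'
#' Each feature's discriminability is its rank-statistic AUC — the
#' probability that a positive sample outranks a negative one, ties
#' counted 1/2 — folded to `max(a, 1 - a)` so direction-reversed features
#' rank by discriminability.  This equals the AUC of a univariate monotone
#' classifier on the feature (such as the per-feature logistic regression),
#' since AUC is invariant to monotone transforms of the score.
#'
#' @inheritParams ttest_filter
#' @return A tibble (`feature`, `auc`) in decreasing AUC order; ties broken
#'   by feature name for determinism.
#' @export
auc_rank <- function(features, labels = NULL) {
  if (is.data.frame(features)) {
    parts <- feature_parts(features)
    x <- parts$x
    labels <- parts$meta$label
  } else {
    x <- as.matrix(features)
  }
  pos <- labels == "positive"
  n_pos <- sum(pos)
  n_neg <- sum(!pos)
  auc <- vapply(seq_len(ncol(x)), function(j) {
    r <- rank(x[, j])          # midranks handle ties (counted 1/2)
    a <- (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
    max(a, 1 - a)
  }, numeric(1))
  tibble::tibble(feature = colnames(x), auc = auc) |>
    dplyr::arrange(dplyr::desc(.data$auc), .data$feature)
}

# 5-fold CV accuracy/MCC of the root-level DPGMM classifier on a feature
# subset: fit on the training folds, label clusters by majority, predict
# the held-out fold by argmax posterior over existing clusters.
cv_dpgmm_performance <- function(x, labels, folds, alpha = 10,
                                 n_iterations = 20L, sigma2 = 1, seed = 1L) {
  accs <- numeric(0)
  mccs <- numeric(0)
  for (f in sort(unique(folds))) {
    tr <- folds != f
    fit <- dpgmm_fit(x[tr, , drop = FALSE], alpha = alpha,
                     n_iterations = n_iterations, sigma2 = sigma2,
                     seed = derive_seed(seed, paste0("fold", f)))
    fit <- label_clusters(fit, labels[tr])
    te <- which(!tr)
    preds <- vapply(te, function(i) {
      a <- dpgmm_assign(x[i, ], fit, include_new = FALSE,
                        seed = derive_seed(seed, paste0("assign", i)))
      fit$cluster_labels[match(a$cluster_id, fit$cluster_ids)]
    }, character(1))
    m <- classification_metrics(labels[te], preds)
    accs <- c(accs, m$accuracy)
    mccs <- c(mccs, m$mcc)
  }
  c(accuracy = mean(accs), mcc = mean(mccs))
}

#' Recursive feature elimination with cross-validated DPGMM performance
#'
#' Starting from all ranked features, the lowest-AUC feature(s) are removed
#' one `step` at a time; after each removal the root-level DPGMM classifier
#' is refitted per cross-validation fold and mean accuracy and MCC are
#' recorded.  Folds are stratified by label and fixed by `seed` across all
#' steps, so the held-out fold never influences the ranking.  The selected
#' set is the smallest feature count whose accuracy is within `tolerance`
#' of the best accuracy seen along the path.
#'
#' @inheritParams ttest_filter
#' @param ranking A tibble from [auc_rank()] covering all feature columns.
#' @param n_folds Number of cross-validation folds.
#' @param step Features removed per step.
#' @param tolerance Accuracy tolerance for "without losing performance".
#' @param seed Integer seed (folds and fits).
#' @param alpha_dp,n_iterations,sigma2 DPGMM parameters for the CV fits.
#' @return A `selection_trace`: list with `rfe_path` (tibble of
#'   `n_features`, `cv_accuracy`, `cv_mcc`), `selected` (feature names),
#'   `auc_ranking`, `full_performance`.
#' @export
run_rfe <- function(features, labels = NULL, ranking = NULL, n_folds = 5L,
                    step = 1L, tolerance = 0.005, seed = 1L, alpha_dp = 10,
                    n_iterations = 20L, sigma2 = 1) {
  if (is.data.frame(features)) {
    parts <- feature_parts(features)
    x <- parts$x
    labels <- parts$meta$label
  } else {
    x <- as.matrix(features)
  }
  if (is.null(ranking)) ranking <- auc_rank(x, labels)
  if (!setequal(ranking$feature, colnames(x))) {
    stop("ranking must cover exactly the feature columns", call. = FALSE)
  }
  folds <- cv_folds(labels, k = n_folds, seed = seed)
  ordered <- ranking$feature              # best first
  m <- length(ordered)
  full_perf <- cv_dpgmm_performance(x, labels, folds, alpha = alpha_dp,
                                    n_iterations = n_iterations,
                                    sigma2 = sigma2, seed = seed)
  path <- list()
  keep <- m
  while (keep - step >= 1L) {
    keep <- keep - step
    sel <- ordered[seq_len(keep)]
    perf <- cv_dpgmm_performance(x[, sel, drop = FALSE], labels, folds,
                                 alpha = alpha_dp, n_iterations = n_iterations,
                                 sigma2 = sigma2, seed = seed)
    path[[length(path) + 1L]] <- tibble::tibble(
      n_features = keep, cv_accuracy = perf[["accuracy"]],
      cv_mcc = perf[["mcc"]])
  }
  rfe_path <- dplyr::bind_rows(path)
  all_path <- dplyr::bind_rows(
    tibble::tibble(n_features = m, cv_accuracy = full_perf[["accuracy"]],
                   cv_mcc = full_perf[["mcc"]]),
    rfe_path)
  best_acc <- max(all_path$cv_accuracy)
  ok <- all_path[all_path$cv_accuracy >= best_acc - tolerance, , drop = FALSE]
  n_sel <- min(ok$n_features)
  trace <- list(
    rfe_path = rfe_path,
    selected = ordered[seq_len(n_sel)],
    auc_ranking = ranking,
    full_performance = tibble::tibble(n_features = m,
                                      cv_accuracy = full_perf[["accuracy"]],
                                      cv_mcc = full_perf[["mcc"]]),
    tolerance = tolerance
  )
  class(trace) <- "selection_trace"
  trace
}

#' @export
print.selection_trace <- function(x, ...) {
  cat(sprintf("Feature-selection trace: %d -> %d features\n",
              x$full_performance$n_features, length(x$selected)))
  cat(sprintf("  best CV accuracy %.3f, selected-set accuracy within %.3f\n",
              max(c(x$full_performance$cv_accuracy, x$rfe_path$cv_accuracy)),
              x$tolerance))
  invisible(x)
}
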