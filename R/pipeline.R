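# End-to-end training: features -> t-test filter -> AUC ranking -> RFE ->
# cascade tree, mirroring how the final model is assembled from its parts.

#' Train a cascade target-prediction model from labelled interactions
#'
#' Runs the full training pipeline: feature generation, the Welch t-test
#' filter, univariate AUC ranking, recursive feature elimination with
#' cross-validated DPGMM accuracy, and finally the cascade tree on the
#' selected, standardized features.
#'
#' @param interactions Labelled interaction tibble (positives and
#'   negatives).
#' @param mirnas,transcripts Sequence tibbles from [read_fasta()].
#' @param config A [feature_config()].
#' @param cascade A [cascade_config()].
#' @param filter_alpha t-test retention threshold.
#' @param rfe Run recursive feature elimination (`TRUE`) or keep all
#'   post-filter features.
#' @param rfe_step Features removed per elimination step; `NULL` chooses a
#'   chunk size giving roughly 15 elimination steps.
#' @param n_folds,tolerance RFE cross-validation folds and accuracy
#'   tolerance.
#' @param seed Integer seed for the selection folds and fits.
#' @return A list of class `mircascade_pipeline` with elements `tree`
#'   (the [build_cascade()] model), `features` (training feature tibble),
#'   `filter`, `ranking`, `selection` (the [run_rfe()] trace or `NULL`),
#'   and `selected` (feature names used by the tree).
#' @export
train_pipeline <- function(interactions, mirnas, transcripts,
                           config = feature_config(),
                           cascade = cascade_config(),
                           filter_alpha = 0.05, rfe = TRUE, rfe_step = NULL,
                           n_folds = 5L, tolerance = 0.005, seed = 1L) {
  feats <- build_feature_matrix(interactions, mirnas, transcripts, config)
  filt <- ttest_filter(feats, alpha = filter_alpha)
  if (length(filt$retained) == 0L) {
    stop("no feature survived the t-test filter", call. = FALSE)
  }
  sub <- select_feature_columns(feats, filt$retained)
  ranking <- auc_rank(sub)
  trace <- NULL
  selected <- filt$retained
  if (rfe) {
    step <- rfe_step %||% max(1L, ceiling(length(filt$retained) / 15))
    trace <- run_rfe(sub, ranking = ranking, n_folds = n_folds, step = step,
                     tolerance = tolerance, seed = seed,
                     n_iterations = 15L)
    selected <- trace$selected
  }
  std <- standardize_features(select_feature_columns(feats, selected))
  tree <- build_cascade(std, cascade)
  structure(list(tree = tree, features = feats, filter = filt,
                 ranking = ranking, selection = trace, selected = selected,
                 feature_config = config),
            class = "mircascade_pipeline")
}

#' Evaluate a trained pipeline on held-out interactions
#'
#' @param pipeline A `mircascade_pipeline` from [train_pipeline()].
#' @param interactions Held-out labelled interactions.
#' @param mirnas,transcripts Sequence tibbles.
#' @param level `"leaf"` or `"root"` classification level.
#' @return A one-row metrics tibble (see [classification_metrics()]).
#' @export
evaluate_pipeline <- function(pipeline, interactions, mirnas, transcripts,
                              level = c("leaf", "root")) {
  level <- match.arg(level)
  feats <- build_feature_matrix(interactions, mirnas, transcripts,
                                pipeline$feature_config)
  feats <- select_feature_columns(feats, pipeline$selected)
  calls <- classify_interactions(feats, pipeline$tree, level = level)
  classification_metrics(interactions$label, calls$predicted_label)
}

#' @export
print.mircascade_pipeline <- function(x, ...) {
  cat(sprintf("mircascade pipeline: %d -> %d features after selection\n",
              length(attr(x$features, "feature_names")), length(x$selected)))
  print(x$tree)
  invisible(x)
}
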