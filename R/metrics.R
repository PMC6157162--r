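# Binary-classification evaluation: sensitivity, specificity, accuracy and
# the Matthews correlation coefficient, with a stratified train/test split.

#' Confusion counts for binary labels
#'
#' @param y_true,y_pred Equal-length character vectors over
#'   `"positive"`/`"negative"` (positive = interacting).
#' @return A one-row tibble with `tp`, `fp`, `tn`, `fn`.
#' @export
confusion <- function(y_true, y_pred) {
  if (length(y_true) == 0L) stop("empty label vectors", call. = FALSE)
  if (length(y_true) != length(y_pred)) {
    stop("y_true and y_pred have different lengths", call. = FALSE)
  }
  ok <- c("positive", "negative")
  if (!all(y_true %in% ok) || !all(y_pred %in% ok)) {
    stop("labels must be 'positive' or 'negative'", call. = FALSE)
  }
  tibble::tibble(
    tp = sum(y_true == "positive" & y_pred == "positive"),
    fp = sum(y_true == "negative" & y_pred == "positive"),
    tn = sum(y_true == "negative" & y_pred == "negative"),
    fn = sum(y_true == "positive" & y_pred == "negative")
  )
}

#' Classification metrics from confusion counts
#'
#' Standard formulas.  `MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`,
#' defined as 0 when any denominator factor is zero.  Sensitivity with no
#' positives (and specificity with no negatives) is reported as `NA`.
#'
#' @param counts A one-row tibble or list with `tp`, `fp`, `tn`, `fn`.
#' @return The metric value.
#' @export
sensitivity <- function(counts) {
  with(counts, if (tp + fn == 0) NA_real_ else tp / (tp + fn))
}

#' @rdname sensitivity
#' @export
specificity <- function(counts) {
  with(counts, if (tn + fp == 0) NA_real_ else tn / (tn + fp))
}

#' @rdname sensitivity
#' @export
accuracy <- function(counts) {
  with(counts, (tp + tn) / (tp + fp + tn + fn))
}

#' @rdname sensitivity
#' @export
mcc <- function(counts) {
  with(counts, {
    denom <- as.numeric(tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
    if (denom == 0) 0 else (as.numeric(tp) * tn - as.numeric(fp) * fn) / sqrt(denom)
  })
}

#' All metrics from raw label vectors
#'
#' @inheritParams confusion
#' @return One-row tibble with counts and all four metrics.
#' @export
classification_metrics <- function(y_true, y_pred) {
  cts <- confusion(y_true, y_pred)
  dplyr::mutate(cts,
                sensitivity = sensitivity(cts),
                specificity = specificity(cts),
                accuracy = accuracy(cts),
                mcc = mcc(cts))
}

#' Stratified train/test split of an interaction table
#'
#' @param interactions A tibble with a `label` column.
#' @param test_fraction Fraction held out for testing (default 0.25).
#' @param seed Integer seed; the split is reproducible.
#' @return A list with `train` and `test` tibbles (disjoint, stratified by
#'   label).
#' @export
split_interactions <- function(interactions, test_fraction = 0.25, seed = 1L) {
  if (!(test_fraction > 0 && test_fraction < 1)) {
    stop("test_fraction must be in (0, 1)", call. = FALSE)
  }
  n <- nrow(interactions)
  if (n < 4L) stop("need at least 4 interactions to split", call. = FALSE)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(derive_seed(seed, "split"))
  test_idx <- integer(0)
  for (lab in unique(interactions$label)) {
    idx <- which(interactions$label == lab)
    n_test <- round(length(idx) * test_fraction)
    test_idx <- c(test_idx, sort(idx[sample.int(length(idx), n_test)]))
  }
  test_idx <- sort(test_idx)
  list(train = interactions[-test_idx, , drop = FALSE],
       test = interactions[test_idx, , drop = FALSE])
}

#' Stratified cross-validation fold assignment
#'
#' @param labels Label vector.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return Integer fold ids (1..k), stratified by label.
#' @export
cv_folds <- function(labels, k = 5L, seed = 1L) {
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(derive_seed(seed, "cv"))
  folds <- integer(length(labels))
  for (lab in unique(labels)) {
    idx <- which(labels == lab)
    folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  folds
}
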