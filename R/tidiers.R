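#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted DPGMM: one row per cluster
#'
#' @param x A `dpgmm_model`.
#' @param ... Unused.
#' @return A tibble with cluster id, size, mixing proportion, label counts
#'   and miRNA composition (where attached by [label_clusters()]).
#' @export
tidy.dpgmm_model <- function(x, ...) {
  K <- length(x$cluster_ids)
  out <- tibble::tibble(
    cluster_id = x$cluster_ids,
    n_j = x$counts,
    proportion = x$counts / x$n
  )
  if (!is.null(x$cluster_labels)) {
    out$label <- x$cluster_labels
    out$n_pos <- x$n_pos
    out$n_neg <- x$n_neg
  }
  if (!is.null(x$dominant_mirna)) {
    out$dominant_mirna <- x$dominant_mirna
    out$c_k <- x$c_k
  }
  out
}

#' One-row summary of a fitted DPGMM
#'
#' @param x A `dpgmm_model`.
#' @param ... Unused.
#' @return A one-row tibble: n, m, K, alpha, sigma2, sweeps, convergence.
#' @export
glance.dpgmm_model <- function(x, ...) {
  tibble::tibble(
    n = x$n, m = x$m, k = length(x$cluster_ids),
    alpha = x$alpha, sigma2 = x$sigma2,
    sweeps = x$sweeps_run, converged = x$converged
  )
}

#' Tidy a cascade tree: one row per node
#'
#' @param x A `cascade_dpgmm`.
#' @param ... Unused.
#' @return The [cascade_nodes()] table.
#' @export
tidy.cascade_dpgmm <- function(x, ...) cascade_nodes(x)

#' One-row summary of a cascade tree
#'
#' @param x A `cascade_dpgmm`.
#' @param ... Unused.
#' @return A one-row tibble with node/leaf counts, depth and the number of
#'   positive and miRNA-homogeneous leaves.
#' @export
glance.cascade_dpgmm <- function(x, ...) {
  nodes <- cascade_nodes(x)
  leaves <- nodes[nodes$status != "internal", , drop = FALSE]
  tibble::tibble(
    n_nodes = nrow(nodes),
    depth = max(nodes$depth),
    n_internal = sum(nodes$status == "internal"),
    n_leaves = nrow(leaves),
    n_excluded = sum(leaves$status == "excluded"),
    n_positive_leaves = sum(leaves$label == "positive" &
                              leaves$status != "excluded"),
    n_homogeneous_mirna = sum(leaves$status == "leaf_homogeneous_mirna")
  )
}

#' Tidy a feature-selection trace: the elimination path
#'
#' @param x A `selection_trace` from [run_rfe()].
#' @param ... Unused.
#' @return Tibble with `n_features`, `cv_accuracy`, `cv_mcc` per step.
#' @export
tidy.selection_trace <- function(x, ...) x$rfe_path

#' One-row summary of a feature-selection trace
#'
#' @param x A `selection_trace`.
#' @param ... Unused.
#' @return A one-row tibble with initial and selected feature counts and
#'   the best cross-validated accuracy.
#' @export
glance.selection_trace <- function(x, ...) {
  tibble::tibble(
    n_initial = x$full_performance$n_features,
    n_selected = length(x$selected),
    best_cv_accuracy = max(c(x$full_performance$cv_accuracy,
                             x$rfe_path$cv_accuracy)),
    tolerance = x$tolerance
  )
}
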