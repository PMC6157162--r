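#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Cluster-size and composition plot for a fitted DPGMM
#'
#' @param object A `dpgmm_model`.
#' @param ... Unused.
#' @return A ggplot: cluster sizes, coloured by majority label when labels
#'   are attached.
#' @export
autoplot.dpgmm_model <- function(object, ...) {
  tab <- tidy(object)
  tab$cluster_id <- factor(tab$cluster_id, levels = tab$cluster_id[order(-tab$n_j)])
  p <- ggplot2::ggplot(tab, ggplot2::aes(x = .data$cluster_id, y = .data$n_j)) +
    ggplot2::labs(x = "cluster", y = "members",
                  title = sprintf("DPGMM: %d clusters (alpha = %g)",
                                  nrow(tab), object$alpha)) +
    ggplot2::theme_minimal()
  if ("label" %in% names(tab)) {
    p + ggplot2::geom_col(ggplot2::aes(fill = .data$label)) +
      ggplot2::scale_fill_manual(values = c(positive = "#2166ac",
                                            negative = "#b2182b"))
  } else {
    p + ggplot2::geom_col(fill = "grey40")
  }
}

#' Tree-structure plot for a cascade model
#'
#' Nodes are laid out by depth; size encodes member count and colour the
#' node status.
#'
#' @param object A `cascade_dpgmm`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cascade_dpgmm <- function(object, ...) {
  nodes <- cascade_nodes(object)
  nodes <- nodes |>
    dplyr::group_by(.data$depth) |>
    dplyr::mutate(xpos = (dplyr::row_number() - 0.5) / dplyr::n()) |>
    dplyr::ungroup()
  edges <- nodes |>
    dplyr::filter(!is.na(.data$parent)) |>
    dplyr::left_join(
      nodes |> dplyr::select(parent_id = "node_id", px = "xpos",
                             pdepth = "depth"),
      by = c(parent = "parent_id"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$px, y = -.data$pdepth, xend = .data$xpos,
                   yend = -.data$depth), colour = "grey70") +
    ggplot2::geom_point(
      data = nodes,
      ggplot2::aes(x = .data$xpos, y = -.data$depth, size = .data$n,
                   colour = .data$status)) +
    ggplot2::scale_y_continuous(breaks = -seq(0, max(nodes$depth)),
                                labels = seq(0, max(nodes$depth))) +
    ggplot2::labs(x = NULL, y = "depth", title = "Cascade cluster tree") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' Elimination-path plot for a feature-selection trace
#'
#' @param object A `selection_trace`.
#' @param ... Unused.
#' @return A ggplot of cross-validated accuracy and MCC against the number
#'   of retained features.
#' @export
autoplot.selection_trace <- function(object, ...) {
  path <- dplyr::bind_rows(object$full_performance, object$rfe_path) |>
    tidyr::pivot_longer(c("cv_accuracy", "cv_mcc"), names_to = "metric")
  ggplot2::ggplot(path, ggplot2::aes(x = .data$n_features, y = .data$value,
                                     colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "features retained", y = NULL,
                  title = "Recursive feature elimination") +
    ggplot2::theme_minimal()
}

#' Regulator-degree distributions of a prediction table
#'
#' @param predictions A tibble from [screen_transcriptome()].
#' @return A ggplot with the targets-per-miRNA and regulators-per-transcript
#'   histograms side by side.
#' @export
plot_regulator_statistics <- function(predictions) {
  stats <- regulator_statistics(predictions)
  df <- dplyr::bind_rows(
    tibble::tibble(panel = "targets per miRNA",
                   count = stats$targets_per_mirna$n_targets),
    tibble::tibble(panel = "regulators per transcript",
                   count = stats$regulators_per_transcript$n_regulators)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$count)) +
    ggplot2::geom_histogram(bins = 20, fill = "grey30") +
    ggplot2::facet_wrap(~panel, scales = "free") +
    ggplot2::labs(x = "count", y = "frequency") +
    ggplot2::theme_minimal()
}
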