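# Cascade (divisive) DPGMM: the root split separates interacting from
# non-interacting sites; mixed clusters with more than `size_threshold`
# members are recursively re-clustered until they are homogeneous in the
# participating miRNA or transcript, too small, or at maximum depth.
# Small clusters that are still mixed in label are excluded from the final
# model (they remain in the tree as terminal sinks with zero confidence).

#' Cascade configuration
#'
#' @param size_threshold Clusters must have *more than* this many members
#'   to be re-clustered (default 30).
#' @param homogeneity Dominant miRNA/mRNA fraction at or above which a
#'   cluster is a homogeneous leaf; in (0, 1].
#' @param max_depth Maximum tree depth (root = depth 0).
#' @param alpha,n_iterations,sigma2 DPGMM parameters used at each split.
#' @param grid `"none"` (fixed `alpha`/`n_iterations` everywhere),
#'   `"root"` (the root split is selected by [dpgmm_grid_search()] over
#'   `alphas` x `iteration_counts` and children reuse the selected
#'   combination), or `"all"` (every internal node runs its own BIC grid —
#'   self-tuning, since the concentration that splits a node depends on its
#'   size).  `TRUE`/`FALSE` are accepted as `"root"`/`"none"`.
#' @param alphas,iteration_counts Grids for the BIC search.
#' @param seed Integer seed.
#' @return A list of class `cascade_config`.
#' @export
cascade_config <- function(size_threshold = 30L, homogeneity = 1.0,
                           max_depth = 5L, alpha = 10, n_iterations = 100L,
                           sigma2 = 1, grid = c("none", "root", "all"),
                           alphas = c(10, 30, 60, 90, 100),
                           iteration_counts = c(10, 30, 60, 90, 100),
                           seed = 1L) {
  if (size_threshold < 1L) stop("size_threshold must be >= 1", call. = FALSE)
  if (!(homogeneity > 0 && homogeneity <= 1)) {
    stop("homogeneity must be in (0, 1]", call. = FALSE)
  }
  if (max_depth < 1L) stop("max_depth must be >= 1", call. = FALSE)
  if (is.logical(grid)) grid <- if (isTRUE(grid)) "root" else "none"
  grid <- match.arg(grid, c("none", "root", "all"))
  structure(list(size_threshold = as.integer(size_threshold),
                 homogeneity = homogeneity, max_depth = as.integer(max_depth),
                 alpha = alpha, n_iterations = as.integer(n_iterations),
                 sigma2 = sigma2, grid = grid, alphas = alphas,
                 iteration_counts = iteration_counts, seed = as.integer(seed)),
            class = "cascade_config")
}

dominant_fraction <- function(ids) {
  if (length(ids) == 0L) return(list(id = NA_character_, fraction = 0))
  tab <- sort(table(ids), decreasing = TRUE)
  list(id = names(tab)[1L], fraction = as.numeric(tab[1L]) / length(ids))
}

#' Build the cascade cluster tree
#'
#' @param features A standardized feature tibble (from
#'   [standardize_features()]) whose metadata columns carry `label`,
#'   `mirna_id` and `transcript_id`.  Unstandardized input is standardized
#'   internally and the parameters stored with the tree.
#' @param config A [cascade_config()].
#' @return A `cascade_dpgmm` object: the node tree plus the feature
#'   registry, standardization parameters and configuration fingerprint
#'   needed to classify new interactions consistently.
#' @export
build_cascade <- function(features, config = cascade_config()) {
  if (is.null(attr(features, "standardization"))) {
    features <- standardize_features(features)
  }
  parts <- feature_parts(features)
  x <- parts$x
  labels <- parts$meta$label
  mirna_ids <- parts$meta$mirna_id
  mrna_ids <- parts$meta$transcript_id
  if (any(!labels %in% c("positive", "negative"))) {
    stop("cascade training needs positive/negative labels", call. = FALSE)
  }

  node_counter <- 0L
  new_node_id <- function() {
    node_counter <<- node_counter + 1L
    paste0("node", node_counter - 1L)
  }

  split_params <- list(alpha = config$alpha,
                       n_iterations = config$n_iterations)

  describe <- function(idx) {
    lab <- labels[idx]
    pos <- sum(lab == "positive")
    mir <- dominant_fraction(mirna_ids[idx])
    mrna <- dominant_fraction(mrna_ids[idx])
    pos_mir <- dominant_fraction(mirna_ids[idx][lab == "positive"])
    list(
      n = length(idx),
      n_pos = pos, n_neg = length(idx) - pos,
      label = if (pos > length(idx) - pos) "positive" else "negative",
      mirna_homogeneity = mir$fraction, mrna_homogeneity = mrna$fraction,
      top_mirna = mir$id,
      dominant_mirna = pos_mir$id, c_k = pos_mir$fraction
    )
  }

  build_node <- function(idx, depth, is_root) {
    d <- describe(idx)
    node <- list(node_id = new_node_id(), depth = depth, n = d$n,
                 label = d$label, dominant_mirna = d$dominant_mirna,
                 c_k = d$c_k, mirna_homogeneity = d$mirna_homogeneity,
                 mrna_homogeneity = d$mrna_homogeneity,
                 members = idx, model = NULL, children = list())
    mixed_label <- d$n_pos > 0L && d$n_neg > 0L

    if (!is_root) {
      if (d$mirna_homogeneity >= config$homogeneity) {
        node$status <- "leaf_homogeneous_mirna"
        return(node)
      }
      if (d$mrna_homogeneity >= config$homogeneity) {
        node$status <- "leaf_homogeneous_mrna"
        return(node)
      }
      if (d$n <= config$size_threshold) {
        node$status <- if (mixed_label) "excluded" else "leaf_small"
        return(node)
      }
      if (depth >= config$max_depth) {
        node$status <- "leaf_maxdepth"
        return(node)
      }
    }

    seed_here <- derive_seed(config$seed, node$node_id)
    # each refinement round re-centres its own input, so the zero-mean base
    # distribution of the mixture matches the data it actually sees
    center <- colMeans(x[idx, , drop = FALSE])
    xc <- sweep(x[idx, , drop = FALSE], 2L, center)
    use_grid <- (config$grid == "all") || (is_root && config$grid == "root")
    if (use_grid) {
      gs <- dpgmm_grid_search(xc, alphas = config$alphas,
                              iteration_counts = config$iteration_counts,
                              sigma2 = config$sigma2, seed = seed_here)
      model <- gs$best_model
      if (is_root && config$grid == "root") {
        split_params$alpha <<- gs$best$alpha
        split_params$n_iterations <<- gs$best$iterations
      }
      node$grid_table <- gs$table
    } else {
      model <- dpgmm_fit(xc, alpha = split_params$alpha,
                         n_iterations = split_params$n_iterations,
                         sigma2 = config$sigma2, seed = seed_here)
    }
    model <- label_clusters(model, labels[idx], mirna_ids[idx])

    if (length(model$cluster_ids) < 2L) {
      # the mixture converged to a single component: the node is itself a
      # final cluster (termination by convergence, not by the size rule,
      # so it is not excluded)
      node$status <- "leaf_converged"
      return(node)
    }

    node$model <- model
    node$center <- center
    node$status <- "internal"
    kids <- list()
    for (cid in model$cluster_ids) {
      child_idx <- idx[model$assignments == cid]
      kids[[as.character(cid)]] <- build_node(child_idx, depth + 1L,
                                              is_root = FALSE)
    }
    node$children <- kids
    node
  }

  root <- build_node(seq_len(nrow(x)), 0L, is_root = TRUE)
  if (!identical(root$status, "internal")) {
    warning("the root DPGMM found a single component; the tree is trivial. ",
            "Consider a smaller concentration (alphas), more features, ",
            "or more data.", call. = FALSE)
  }
  tree <- list(
    root = root,
    config = unclass(config),
    feature_names = parts$feature_names,
    fingerprint = attr(features, "fingerprint") %||% "unknown",
    standardization = list(
      mean = attr(features, "standardization")$mean,
      sd = attr(features, "standardization")$sd,
      zero_variance = attr(features, "standardization")$zero_variance
    ),
    seed = config$seed
  )
  class(tree) <- "cascade_dpgmm"
  tree
}

#' Interaction confidence score
#'
#' `IC = z * c_k`: the product of the normalized leaf assignment
#' probability `z` and the proportion `c_k` of the leaf's dominant miRNA.
#' Monotone non-decreasing in each argument.
#'
#' @param z Normalized assignment probability in `[0, 1]`.
#' @param c_k Dominant-miRNA proportion in `[0, 1]`.
#' @return `z * c_k`.
#' @export
interaction_confidence <- function(z, c_k) {
  if (any(!is.finite(z)) || any(z < 0 | z > 1)) {
    stop("z must be in [0, 1]", call. = FALSE)
  }
  if (any(!is.finite(c_k)) || any(c_k < 0 | c_k > 1)) {
    stop("c_k must be in [0, 1]", call. = FALSE)
  }
  z * c_k
}

# Route one standardized vector through the tree.  No new-cluster option at
# inference time: a probe is always routed to an existing child.
route_vector <- function(xv, tree, level = c("leaf", "root"), seed = NULL) {
  level <- match.arg(level)
  node <- tree$root
  path <- list()
  z <- NA_real_
  while (identical(node$status, "internal")) {
    post <- dpgmm_posteriors(xv - (node$center %||% 0), node$model,
                             include_new = FALSE)
    w <- if (is.null(seed)) {
      argmax_tiebreak(post$log_posterior)
    } else {
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      set.seed(derive_seed(seed, node$node_id))
      res <- argmax_tiebreak(post$log_posterior)
      if (!is.null(old)) assign(".Random.seed", old, globalenv())
      res
    }
    cid <- post$cluster_id[w]
    z <- post$posterior[w]
    path[[length(path) + 1L]] <- list(node_id = node$node_id,
                                      cluster_id = cid, posterior = z)
    node <- node$children[[as.character(cid)]]
    if (level == "root") break
  }
  excluded <- identical(node$status, "excluded")
  c_k <- if (excluded) 0 else node$c_k
  if (is.na(z)) z <- 1  # degenerate tree: the root itself is terminal
  list(leaf = node, path = path, z = z,
       predicted_label = node$label,
       dominant_mirna = node$dominant_mirna,
       c_k = c_k,
       ic = if (excluded) 0 else interaction_confidence(z, c_k %||% 0))
}

#' Classify interactions through a cascade tree
#'
#' Each feature vector descends the tree by argmax normalized posterior at
#' every internal node (no new-cluster option at inference time).  With
#' `level = "root"` the routing stops after the first split (is the
#' interaction genuine?); with `level = "leaf"` it continues to a terminal
#' node (which miRNA-specific cluster does it belong to?).  Probes landing
#' in an excluded node receive the node's majority label with `ic = 0`.
#'
#' @param features Feature tibble for the probes (raw; standardized
#'   internally with the tree's training-time parameters) or a numeric
#'   matrix already standardized.
#' @param tree A fitted `cascade_dpgmm`.
#' @param level `"leaf"` (default) or `"root"`.
#' @param seed Optional seed making tie-breaks reproducible.
#' @return A tibble with one row per probe: `interaction_id`, `leaf_node`,
#'   `leaf_status`, `predicted_label`, `z` (the stopping node's normalized
#'   posterior), `dominant_mirna`, `c_k`, `ic`, and a `path` list-column of
#'   per-step (node, cluster, posterior) records.
#' @export
classify_interactions <- function(features, tree, level = c("leaf", "root"),
                                  seed = NULL) {
  level <- match.arg(level)
  stopifnot(inherits(tree, "cascade_dpgmm"))
  if (is.data.frame(features)) {
    fp <- attr(features, "fingerprint")
    if (!is.null(fp) && !identical(fp, tree$fingerprint)) {
      stop("feature configuration fingerprint does not match the trained model",
           call. = FALSE)
    }
    if (is.null(attr(features, "standardization"))) {
      features <- apply_standardization(features, tree$standardization)
    }
    parts <- feature_parts(features)
    x <- parts$x
    ids <- parts$meta$interaction_id
  } else {
    x <- as.matrix(features)
    ids <- rownames(x) %||% as.character(seq_len(nrow(x)))
  }
  if (ncol(x) != length(tree$feature_names)) {
    stop(sprintf("probe has %d features, model expects %d", ncol(x),
                 length(tree$feature_names)), call. = FALSE)
  }
  rows <- lapply(seq_len(nrow(x)), function(i) {
    r <- route_vector(x[i, ], tree, level = level, seed = seed)
    tibble::tibble(
      interaction_id = ids[i],
      leaf_node = r$leaf$node_id,
      leaf_status = r$leaf$status,
      predicted_label = r$predicted_label,
      z = r$z,
      dominant_mirna = r$dominant_mirna %||% NA_character_,
      c_k = r$c_k %||% 0,
      ic = r$ic,
      path = list(r$path)
    )
  })
  dplyr::bind_rows(rows)
}

#' Flatten a cascade tree into a per-node table
#'
#' @param tree A `cascade_dpgmm`.
#' @return A tibble with one row per node: id, depth, status, size, label,
#'   homogeneity statistics and member count by class.
#' @export
cascade_nodes <- function(tree) {
  stopifnot(inherits(tree, "cascade_dpgmm"))
  acc <- list()
  walk <- function(node, parent) {
    acc[[length(acc) + 1L]] <<- tibble::tibble(
      node_id = node$node_id, parent = parent, depth = node$depth,
      status = node$status, n = node$n, label = node$label,
      dominant_mirna = node$dominant_mirna %||% NA_character_,
      c_k = node$c_k %||% NA_real_,
      mirna_homogeneity = node$mirna_homogeneity %||% NA_real_,
      mrna_homogeneity = node$mrna_homogeneity %||% NA_real_,
      n_children = length(node$children)
    )
    for (ch in node$children) walk(ch, node$node_id)
  }
  walk(tree$root, NA_character_)
  dplyr::bind_rows(acc)
}

#' Homogeneity profile of the positive leaves
#'
#' For each threshold, counts the positive leaf clusters whose
#' dominant-miRNA fraction reaches the threshold — the cascade's
#' miRNA-specialization summary.
#'
#' @param tree A `cascade_dpgmm`.
#' @param thresholds Homogeneity thresholds in `[0, 1]`.
#' @return A tibble with `threshold`, `n_positive_leaves`,
#'   `n_homogeneous`, `fraction`.
#' @export
homogeneity_profile <- function(tree, thresholds = c(0.8, 0.9, 1.0)) {
  nodes <- cascade_nodes(tree)
  leaves <- dplyr::filter(nodes, .data$status != "internal",
                          .data$status != "excluded",
                          .data$label == "positive")
  purrr::map_dfr(thresholds, function(h) {
    n_hom <- sum(leaves$mirna_homogeneity >= h)
    tibble::tibble(threshold = h,
                   n_positive_leaves = nrow(leaves),
                   n_homogeneous = n_hom,
                   fraction = if (nrow(leaves) > 0L) n_hom / nrow(leaves) else NA_real_)
  })
}

#' @export
print.cascade_dpgmm <- function(x, ...) {
  nodes <- cascade_nodes(x)
  cat(sprintf("Cascade DPGMM tree: %d nodes, depth %d\n",
              nrow(nodes), max(nodes$depth)))
  cat(sprintf("  %d internal, %d leaves (%d excluded)\n",
              sum(nodes$status == "internal"),
              sum(nodes$status != "internal"),
              sum(nodes$status == "excluded")))
  tab <- table(nodes$status)
  for (s in names(tab)) cat(sprintf("  %-24s %d\n", s, tab[[s]]))
  invisible(x)
}
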