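# Dirichlet-process Gaussian mixture model with a Chinese-restaurant-process
# prior, fixed isotropic component variance sigma2, and a conjugate N(0, 1)
# prior on component means (data are assumed standardized).  Assignment is
# MAP-style: each point goes to the option with the highest normalized
# posterior; exact ties are broken uniformly at random under the model seed.

#' Chinese-restaurant-process prior masses
#'
#' For a point joining a partition of the other `n - 1` points, an existing
#' cluster j with n_j members has prior mass n_j / (alpha + n - 1) and a new
#' cluster has mass alpha / (alpha + n - 1).  With sum(n_j) = n - 1 these
#' masses sum to one exactly.
#'
#' @param n_j Number of points already in the cluster.
#' @param alpha Concentration parameter (> 0).
#' @param n Total number of data points (including the one being assigned).
#' @return Prior probability mass.
#' @examples
#' crp_prior(9, alpha = 10, n = 100)   # 9/109
#' crp_prior_new(10, n = 1)            # first point: always a new cluster
#' @export
crp_prior <- function(n_j, alpha, n) {
  assert_scalar_number(alpha, "alpha", 0, strict = TRUE)
  stopifnot(n >= 1, all(n_j >= 0))
  n_j / (alpha + n - 1)
}

#' @rdname crp_prior
#' @export
crp_prior_new <- function(alpha, n) {
  assert_scalar_number(alpha, "alpha", 0, strict = TRUE)
  stopifnot(n >= 1)
  alpha / (alpha + n - 1)
}

# Posterior mean of each cluster under the conjugate N(0,1) prior:
# mu_j = sum_vector / (n_j + sigma2).
dpgmm_posterior_means <- function(sums, counts, sigma2) {
  if (length(counts) == 0L) return(sums)
  sums / (counts + sigma2)
}

# Log densities of x under each existing cluster (isotropic N(mu_j, sigma2 I))
# plus, optionally, the new-cluster option (prior predictive N(0, (sigma2+1) I),
# the conjugate N(0,1) prior on the mean integrated out).  Adds the CRP terms
# log(n_j) / log(alpha).
dpgmm_log_post_vec <- function(x, means, counts, alpha, sigma2,
                               include_new = TRUE) {
  m <- length(x)
  lp <- numeric(0)
  if (length(counts) > 0L) {
    d2 <- rowSums((means - matrix(x, nrow = nrow(means), ncol = m,
                                  byrow = TRUE))^2)
    lp <- log(counts) - 0.5 * m * log(2 * pi * sigma2) - d2 / (2 * sigma2)
  }
  if (include_new) {
    v <- sigma2 + 1
    lp_new <- log(alpha) - 0.5 * m * log(2 * pi * v) - sum(x^2) / (2 * v)
    lp <- c(lp, lp_new)
  }
  lp
}

#' Log posterior of a point under one cluster (or a new cluster)
#'
#' For an existing cluster j the unnormalized log posterior is
#' `log(n_j) + log N(x; mu_j, sigma2 I)`; for a new cluster it is
#' `log(alpha) + log N(x; 0, (sigma2 + 1) I)` (the conjugate standard-normal
#' prior on the mean integrated out).  Normalized assignment probabilities
#' are obtained with [dpgmm_posteriors()] via log-sum-exp.
#'
#' @param x Numeric vector of length `model$m`.
#' @param model A fitted [dpgmm_fit()] model.
#' @param cluster A cluster id present in the model, or `"new"`.
#' @return The unnormalized log posterior.
#' @export
log_posterior <- function(x, model, cluster) {
  stopifnot(inherits(model, "dpgmm_model"))
  if (length(x) != model$m) {
    stop(sprintf("x has %d dimensions, model expects %d", length(x), model$m),
         call. = FALSE)
  }
  lp <- dpgmm_log_post_vec(x, model$means, model$counts, model$alpha,
                           model$sigma2, include_new = TRUE)
  if (identical(cluster, "new")) return(lp[length(lp)])
  j <- match(cluster, model$cluster_ids)
  if (is.na(j)) stop("unknown cluster id: ", cluster, call. = FALSE)
  lp[j]
}

#' Normalized assignment probabilities of a point
#'
#' @param x Numeric vector of length `model$m`.
#' @param model A fitted model.
#' @param include_new Include the new-cluster option.
#' @return A tibble with `cluster_id` (`NA` for the new-cluster option),
#'   `log_posterior` and the normalized probability `posterior`.
#' @export
dpgmm_posteriors <- function(x, model, include_new = TRUE) {
  stopifnot(inherits(model, "dpgmm_model"))
  if (length(x) != model$m) {
    stop(sprintf("x has %d dimensions, model expects %d", length(x), model$m),
         call. = FALSE)
  }
  lp <- dpgmm_log_post_vec(x, model$means, model$counts, model$alpha,
                           model$sigma2, include_new = include_new)
  ids <- model$cluster_ids
  if (include_new) ids <- c(ids, NA_integer_)
  tibble::tibble(cluster_id = ids, log_posterior = lp,
                 posterior = exp(lp - logsumexp(lp)))
}

# argmax with uniform tie-breaking (ties = within `tol` of the maximum),
# consuming the current RNG stream only when a tie occurs.
argmax_tiebreak <- function(lp, tol = 1e-12) {
  cand <- which(lp >= max(lp) - tol)
  if (length(cand) == 1L) return(cand)
  cand[sample.int(length(cand), 1L)]
}

#' Assign a new observation to a cluster
#'
#' The observation goes to the option (existing cluster or, optionally, a
#' new cluster) with the highest normalized posterior; exact ties are
#' broken uniformly at random.
#'
#' @param x Numeric vector.
#' @param model Fitted model.
#' @param include_new Allow the new-cluster option.
#' @param seed Optional integer; when given, the tie-break RNG is seeded
#'   locally so the call is reproducible.
#' @return A one-row tibble with `cluster_id` (`NA` for a new cluster) and
#'   the winning normalized posterior `z`.
#' @export
dpgmm_assign <- function(x, model, include_new = TRUE, seed = NULL) {
  post <- dpgmm_posteriors(x, model, include_new = include_new)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  w <- argmax_tiebreak(post$log_posterior)
  tibble::tibble(cluster_id = post$cluster_id[w], z = post$posterior[w])
}

#' Fit a Dirichlet-process Gaussian mixture by MAP sweeps
#'
#' Points are first assigned sequentially in a seed-shuffled order (each
#' point sees the clusters created so far plus a new-cluster option), then
#' refined with collapsed sweeps: one point at a time is removed from its
#' cluster, posteriors over all options are recomputed, and the point is
#' reassigned to the argmax.  Empty clusters are deleted immediately;
#' cluster ids are assigned in birth order and never reused.  The fit runs
#' `n_iterations` sweeps, stopping early when a full sweep changes no
#' assignment.
#'
#' @param x Numeric matrix (rows = observations) or a standardized feature
#'   tibble from [standardize_features()].
#' @param alpha Concentration parameter (> 0).
#' @param n_iterations Maximum number of refinement sweeps.
#' @param sigma2 Fixed isotropic component variance.
#' @param seed Integer seed controlling the visit order and tie-breaks.
#' @param sample_assignments If `TRUE`, assignments are drawn from the
#'   normalized posterior (stochastic Gibbs) instead of the argmax; a
#'   diagnostic mode, not used by the trained models.
#' @return A `dpgmm_model` object.
#' @export
dpgmm_fit <- function(x, alpha = 10, n_iterations = 100L, sigma2 = 1,
                      seed = 1L, sample_assignments = FALSE) {
  if (is.data.frame(x)) x <- feature_parts(x)$x
  x <- as.matrix(x)
  assert_scalar_number(alpha, "alpha", 0, strict = TRUE)
  assert_scalar_number(sigma2, "sigma2", 0, strict = TRUE)
  if (any(!is.finite(x))) stop("non-finite feature values", call. = FALSE)
  seed <- as.integer(seed)
  n <- nrow(x)
  m <- ncol(x)
  if (n < 2L) stop("need at least 2 observations", call. = FALSE)

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  visit <- sample.int(n)

  ids <- integer(0)
  counts <- integer(0)
  sums <- matrix(0, nrow = 0L, ncol = m)
  z <- integer(n)          # index into ids/counts/sums (0 = unassigned)
  next_id <- 1L

  pick <- function(lp) {
    if (sample_assignments) {
      p <- exp(lp - logsumexp(lp))
      sample.int(length(lp), 1L, prob = p)
    } else {
      argmax_tiebreak(lp)
    }
  }
  place <- function(i, w) {
    K <- length(ids)
    if (w > K) {
      ids <<- c(ids, next_id)
      next_id <<- next_id + 1L
      counts <<- c(counts, 1L)
      sums <<- rbind(sums, x[i, ])
      z[i] <<- length(ids)
    } else {
      counts[w] <<- counts[w] + 1L
      sums[w, ] <<- sums[w, ] + x[i, ]
      z[i] <<- w
    }
  }

  # sequential CRP initialization
  for (i in visit) {
    means <- dpgmm_posterior_means(sums, counts, sigma2)
    lp <- dpgmm_log_post_vec(x[i, ], means, counts, alpha, sigma2)
    place(i, pick(lp))
  }

  sweeps_run <- 0L
  converged <- FALSE
  for (sweep in seq_len(n_iterations)) {
    changed <- FALSE
    for (i in visit) {
      w_old <- z[i]
      old_id <- ids[w_old]
      counts[w_old] <- counts[w_old] - 1L
      sums[w_old, ] <- sums[w_old, ] - x[i, ]
      if (counts[w_old] == 0L) {
        ids <- ids[-w_old]
        counts <- counts[-w_old]
        sums <- sums[-w_old, , drop = FALSE]
        z[z > w_old] <- z[z > w_old] - 1L
        z[i] <- 0L
      }
      means <- dpgmm_posterior_means(sums, counts, sigma2)
      lp <- dpgmm_log_post_vec(x[i, ], means, counts, alpha, sigma2)
      w <- pick(lp)
      place(i, w)
      if (ids[z[i]] != old_id) changed <- TRUE
    }
    sweeps_run <- sweep
    if (!changed) {
      converged <- TRUE
      break
    }
  }

  fn <- colnames(x) %||% paste0("V", seq_len(m))
  dimnames(sums) <- list(NULL, fn)
  model <- list(
    alpha = alpha, sigma2 = sigma2, n = n, m = m,
    feature_names = fn,
    seed = seed, n_iterations = as.integer(n_iterations),
    sweeps_run = sweeps_run, converged = converged,
    next_cluster_id = next_id,
    cluster_ids = ids,
    counts = counts,
    sums = sums,
    means = dpgmm_posterior_means(sums, counts, sigma2),
    assignments = ids[z]
  )
  class(model) <- "dpgmm_model"
  model
}

#' Attach majority labels and miRNA composition to fitted clusters
#'
#' A cluster is labeled positive iff its positive members strictly
#' outnumber its negative members; ties are labeled negative (conservative
#' for target prediction).  The dominant miRNA and its proportion `c_k`
#' are computed over the cluster's positive members.
#'
#' @param model A fitted `dpgmm_model`.
#' @param labels Character vector (`"positive"`/`"negative"`) aligned with
#'   the training rows.
#' @param mirna_ids Optional character vector of miRNA ids aligned with the
#'   training rows.
#' @return The model with `cluster_labels`, `n_pos`, `n_neg`, and (when
#'   miRNA ids are given) `dominant_mirna` and `c_k` fields.
#' @export
label_clusters <- function(model, labels, mirna_ids = NULL) {
  stopifnot(inherits(model, "dpgmm_model"))
  if (length(labels) != model$n || any(is.na(labels))) {
    stop("every training point needs a label", call. = FALSE)
  }
  if (!all(labels %in% c("positive", "negative"))) {
    stop("labels must be 'positive' or 'negative'", call. = FALSE)
  }
  K <- length(model$cluster_ids)
  n_pos <- integer(K)
  n_neg <- integer(K)
  dominant <- rep(NA_character_, K)
  c_k <- numeric(K)
  for (j in seq_len(K)) {
    members <- model$assignments == model$cluster_ids[j]
    n_pos[j] <- sum(labels[members] == "positive")
    n_neg[j] <- sum(labels[members] == "negative")
    if (!is.null(mirna_ids)) {
      pos_mirnas <- mirna_ids[members & labels == "positive"]
      if (length(pos_mirnas) > 0L) {
        tab <- sort(table(pos_mirnas), decreasing = TRUE)
        dominant[j] <- names(tab)[1L]
        c_k[j] <- as.numeric(tab[1L]) / length(pos_mirnas)
      }
    }
  }
  model$n_pos <- n_pos
  model$n_neg <- n_neg
  model$cluster_labels <- ifelse(n_pos > n_neg, "positive", "negative")
  if (!is.null(mirna_ids)) {
    model$dominant_mirna <- dominant
    model$c_k <- c_k
  }
  model
}

# Mixture log-likelihood of `x` under the fitted model: weights n_j/n,
# component densities N(mu_j, sigma2 I).
dpgmm_loglik <- function(model, x) {
  if (is.data.frame(x)) x <- feature_parts(x)$x
  x <- as.matrix(x)
  stopifnot(ncol(x) == model$m)
  w <- model$counts / model$n
  const <- -0.5 * model$m * log(2 * pi * model$sigma2)
  ll <- 0
  for (i in seq_len(nrow(x))) {
    d2 <- rowSums((model$means - matrix(x[i, ], nrow = length(w),
                                        ncol = model$m, byrow = TRUE))^2)
    ll <- ll + logsumexp(log(w) + const - d2 / (2 * model$sigma2))
  }
  ll
}

#' Bayesian information criterion of a fitted mixture
#'
#' `BIC = -2 log L + p log n` with `p = K * m + 1` free parameters (the K
#' component means plus the concentration parameter).
#'
#' @param model Fitted `dpgmm_model`.
#' @param x The data the model was fitted on.
#' @return The BIC value (smaller is better).
#' @export
dpgmm_bic <- function(model, x) {
  if (is.data.frame(x)) x <- feature_parts(x)$x
  p <- length(model$cluster_ids) * model$m + 1
  -2 * dpgmm_loglik(model, x) + p * log(model$n)
}

#' Grid search over concentration and sweep counts
#'
#' Fits a model for every combination of `alphas` and `iteration_counts`
#' and returns the combination with the smallest [dpgmm_bic()], together
#' with the full grid table.
#'
#' @param x Data matrix or standardized feature tibble.
#' @param alphas Candidate concentration parameters.
#' @param iteration_counts Candidate sweep counts.
#' @param sigma2 Fixed component variance.
#' @param seed Seed passed to every fit.
#' @return A list with `best_model`, `best` (one-row tibble) and `table`
#'   (tibble with `alpha`, `iterations`, `k`, `bic`).
#' @export
dpgmm_grid_search <- function(x, alphas = c(10, 30, 60, 90, 100),
                              iteration_counts = c(10, 30, 60, 90, 100),
                              sigma2 = 1, seed = 1L) {
  if (length(alphas) == 0L || length(iteration_counts) == 0L) {
    stop("empty parameter grid", call. = FALSE)
  }
  if (is.data.frame(x)) x <- feature_parts(x)$x
  grid <- tidyr::expand_grid(alpha = alphas, iterations = iteration_counts)
  fits <- purrr::pmap(grid, function(alpha, iterations) {
    dpgmm_fit(x, alpha = alpha, n_iterations = iterations, sigma2 = sigma2,
              seed = seed)
  })
  tab <- grid |>
    dplyr::mutate(
      k = purrr::map_int(fits, ~ length(.x$cluster_ids)),
      bic = purrr::map_dbl(fits, dpgmm_bic, x = x)
    )
  best_i <- which.min(tab$bic)
  list(best_model = fits[[best_i]], best = tab[best_i, ], table = tab)
}

#' Exact collapsed log joint of a partition
#'
#' The log of the Chinese-restaurant-process partition probability plus,
#' for each cluster, the closed-form marginal likelihood of its members
#' under the model (mean drawn from N(0, I), observations N(mean,
#' sigma2 I)).  Used to compare whole partitions, e.g. across restarts or
#' against exhaustive enumeration on small instances.
#'
#' @param x Data matrix.
#' @param partition Integer vector of cluster memberships (any coding).
#' @param alpha Concentration parameter.
#' @param sigma2 Component variance.
#' @return The collapsed log joint probability of (partition, data).
#' @export
collapsed_log_joint <- function(x, partition, alpha, sigma2 = 1) {
  x <- as.matrix(x)
  n <- nrow(x)
  stopifnot(length(partition) == n)
  ks <- unique(partition)
  lp <- length(ks) * log(alpha) + lgamma(alpha) - lgamma(alpha + n)
  for (k in ks) {
    xi <- x[partition == k, , drop = FALSE]
    nj <- nrow(xi)
    lp <- lp + lgamma(nj)
    # per-dimension marginal: y ~ N(0, sigma2 I + J)
    logdet <- (nj - 1) * log(sigma2) + log(sigma2 + nj)
    ssq <- colSums(xi^2)
    s1 <- colSums(xi)
    quad <- (ssq - s1^2 / (sigma2 + nj)) / sigma2
    lp <- lp + sum(-0.5 * (nj * log(2 * pi) + logdet + quad))
  }
  lp
}

#' Multi-restart fitting, keeping the best collapsed-objective partition
#'
#' Runs [dpgmm_fit()] under `restarts` derived seeds and returns the model
#' whose final partition has the highest [collapsed_log_joint()].
#'
#' @inheritParams dpgmm_fit
#' @param restarts Number of restarts.
#' @return The best `dpgmm_model`, with the objective in field
#'   `$collapsed_objective`.
#' @export
dpgmm_fit_restarts <- function(x, restarts = 100L, alpha = 1,
                               n_iterations = 50L, sigma2 = 1, seed = 1L) {
  if (is.data.frame(x)) x <- feature_parts(x)$x
  x <- as.matrix(x)
  best <- NULL
  best_obj <- -Inf
  for (r in seq_len(restarts)) {
    fit <- dpgmm_fit(x, alpha = alpha, n_iterations = n_iterations,
                     sigma2 = sigma2, seed = derive_seed(seed, paste0("restart", r)))
    obj <- collapsed_log_joint(x, fit$assignments, alpha, sigma2)
    if (obj > best_obj) {
      best <- fit
      best_obj <- obj
    }
  }
  best$collapsed_objective <- best_obj
  best
}

#' @export
print.dpgmm_model <- function(x, ...) {
  cat(sprintf("DPGMM model: n = %d, m = %d, K = %d clusters\n",
              x$n, x$m, length(x$cluster_ids)))
  cat(sprintf("  alpha = %g, sigma2 = %g, sweeps = %d%s\n",
              x$alpha, x$sigma2, x$sweeps_run,
              if (x$converged) " (converged)" else ""))
  if (!is.null(x$cluster_labels)) {
    cat(sprintf("  %d positive / %d negative clusters\n",
                sum(x$cluster_labels == "positive"),
                sum(x$cluster_labels == "negative")))
  }
  invisible(x)
}
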