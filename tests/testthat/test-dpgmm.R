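test_that("CRP prior masses match the closed form and normalize", {
  expect_equal(crp_prior(9, alpha = 10, n = 100), 9 / 109)
  expect_equal(crp_prior_new(10, n = 1), 1)   # first point: forced new cluster
  expect_error(crp_prior(5, alpha = -1, n = 10), "alpha")

  set.seed(41)
  for (rep in 1:50) {
    alpha <- runif(1, 0.1, 50)
    n <- sample(2:200, 1)
    sizes <- as.vector(table(sample.int(sample(1:8, 1), n - 1, replace = TRUE)))
    total <- sum(crp_prior(sizes, alpha, n)) + crp_prior_new(alpha, n)
    expect_equal(total, 1, tolerance = 1e-14)
  }
})

test_that("log posteriors follow the stated Gaussian forms", {
  # one cluster holding a single point at 2: posterior mean 2/(1+1) = 1
  m <- dpgmm_fit(matrix(c(2, 2), ncol = 1), alpha = 1, n_iterations = 1,
                 seed = 1)
  expect_equal(length(m$cluster_ids), 1)
  mu <- unname(m$means[1, 1])
  x <- mu
  lp_existing <- log_posterior(x, m, m$cluster_ids[1])
  lp_new <- log_posterior(x, m, "new")
  expect_equal(lp_existing, log(2) + dnorm(x, mu, 1, log = TRUE))
  expect_equal(lp_new, log(1) + dnorm(x, 0, sqrt(2), log = TRUE))
  expect_error(log_posterior(c(1, 2), m, "new"), "dimensions")
})

test_that("normalized posteriors sum to one and are shift-invariant", {
  g <- make_gaussian_fixture(K = 2, m = 2, separation = 6,
                             n_per_cluster = 25, seed = 3)
  fit <- dpgmm_fit(g$x, alpha = 1, n_iterations = 20, seed = 3)
  set.seed(4)
  for (rep in 1:20) {
    x <- rnorm(2, sd = 4)
    post <- dpgmm_posteriors(x, fit)
    expect_equal(sum(post$posterior), 1, tolerance = 1e-12)
    # shifting all log posteriors by a constant leaves probabilities alone
    lp <- post$log_posterior - max(post$log_posterior)
    expect_equal(exp(lp) / sum(exp(lp)), post$posterior, tolerance = 1e-12)
  }
})

test_that("assignment is argmax with uniform random tie-breaking", {
  g <- make_gaussian_fixture(K = 1, m = 1, separation = 1,
                             n_per_cluster = 50, seed = 5)
  fit <- dpgmm_fit(g$x - mean(g$x), alpha = 0.01, n_iterations = 10, seed = 5)
  a <- dpgmm_assign(0, fit, seed = 1)
  expect_equal(a$cluster_id, fit$cluster_ids[1])   # alpha << n_j
  expect_true(a$z > 0 && a$z <= 1)

  # two exactly symmetric clusters: ties resolved ~uniformly
  twin <- list(alpha = 1, sigma2 = 1, n = 20L, m = 1L, feature_names = "f1",
               cluster_ids = c(1L, 2L), counts = c(10L, 10L),
               sums = matrix(c(-30, 30), 2, 1), seed = 1L,
               n_iterations = 0L, sweeps_run = 0L, converged = TRUE,
               next_cluster_id = 3L, assignments = rep(c(1L, 2L), each = 10))
  twin$means <- matrix(c(-30, 30), 2, 1) / (10 + 1)
  class(twin) <- "dpgmm_model"
  set.seed(99)
  picks <- replicate(4000, dpgmm_assign(0, twin, include_new = FALSE)$cluster_id)
  p_hat <- mean(picks == 1L)
  se <- sqrt(0.25 / 4000)
  expect_lt(abs(p_hat - 0.5), 3 * se)
})

test_that("fitting recovers well-separated Gaussian structure deterministically", {
  g <- make_gaussian_fixture(K = 3, m = 2, separation = 10,
                             n_per_cluster = 100, seed = 7)
  fit <- dpgmm_fit(g$x, alpha = 1, n_iterations = 100, seed = 11)
  expect_equal(length(fit$cluster_ids), 3)
  expect_gte(oracle_ari(fit$assignments, g$labels), 0.95)
  expect_equal(sum(fit$counts), fit$n)

  refit <- dpgmm_fit(g$x, alpha = 1, n_iterations = 100, seed = 11)
  expect_identical(refit$assignments, fit$assignments)

  # refinement sweeps never reduce the training-data likelihood
  init <- dpgmm_fit(g$x, alpha = 1, n_iterations = 0, seed = 11)
  expect_gte(mircascade:::dpgmm_loglik(fit, g$x),
             mircascade:::dpgmm_loglik(init, g$x))
})

test_that("two identical points form one cluster under a small alpha", {
  x <- matrix(c(0.5, 0.5), ncol = 1)
  fit <- dpgmm_fit(x, alpha = 0.1, n_iterations = 10, seed = 1)
  expect_equal(length(fit$cluster_ids), 1)
  expect_equal(fit$counts, 2L)
})

test_that("non-finite input is rejected before fitting", {
  x <- matrix(c(1, NA, 2, 3), 2)
  expect_error(dpgmm_fit(x), "non-finite")
})

test_that("single-cluster likelihood matches the closed-form Gaussian sum", {
  set.seed(13)
  x <- matrix(rnorm(60), ncol = 2)
  one <- list(alpha = 1, sigma2 = 1, n = 30L, m = 2L,
              feature_names = c("f1", "f2"), cluster_ids = 1L, counts = 30L,
              sums = matrix(colSums(x), 1), seed = 1L, n_iterations = 0L,
              sweeps_run = 0L, converged = TRUE, next_cluster_id = 2L,
              assignments = rep(1L, 30))
  one$means <- one$sums / (30 + 1)
  class(one) <- "dpgmm_model"
  mu <- as.numeric(one$means)
  ll_closed <- sum(dnorm(x[, 1], mu[1], 1, log = TRUE)) +
    sum(dnorm(x[, 2], mu[2], 1, log = TRUE))
  expect_equal(mircascade:::dpgmm_loglik(one, x), ll_closed, tolerance = 1e-9)
  expect_equal(dpgmm_bic(one, x), -2 * ll_closed + 3 * log(30))
})

test_that("duplicating a cluster leaves the likelihood but raises BIC", {
  g <- make_gaussian_fixture(K = 2, m = 2, separation = 8,
                             n_per_cluster = 30, seed = 9)
  fit <- dpgmm_fit(g$x, alpha = 1, n_iterations = 30, seed = 9)
  dup <- fit
  j <- 1L
  half <- fit$counts[j] %/% 2L
  dup$cluster_ids <- c(fit$cluster_ids, max(fit$cluster_ids) + 1L)
  dup$counts <- c(fit$counts, half)
  dup$counts[j] <- fit$counts[j] - half
  dup$sums <- rbind(fit$sums, fit$sums[j, ] * (half / fit$counts[j]))
  dup$means <- rbind(fit$means, fit$means[j, , drop = FALSE])
  ll0 <- mircascade:::dpgmm_loglik(fit, g$x)
  ll1 <- mircascade:::dpgmm_loglik(dup, g$x)
  expect_equal(ll1, ll0, tolerance = 1e-9)   # same mixture density
  expect_gt(dpgmm_bic(dup, g$x), dpgmm_bic(fit, g$x))
})

test_that("cluster labels follow strict majority with ties negative", {
  g <- make_gaussian_fixture(K = 2, m = 1, separation = 12,
                             n_per_cluster = 10, seed = 15)
  fit <- dpgmm_fit(g$x, alpha = 0.5, n_iterations = 30, seed = 15)
  expect_equal(length(fit$cluster_ids), 2)
  # cluster 1 members: 6 pos / 4 neg -> positive; cluster 2: 5/5 -> negative
  labels <- character(20)
  c1 <- fit$assignments == fit$cluster_ids[1]
  labels[c1] <- rep(c("positive", "negative"),
                    c(6, sum(c1) - 6))[seq_len(sum(c1))]
  labels[!c1] <- rep(c("positive", "negative"),
                     c(5, sum(!c1) - 5))[seq_len(sum(!c1))]
  lab <- label_clusters(fit, labels, mirna_ids = rep(c("mA", "mB"), 10))
  expect_equal(lab$cluster_labels[1], "positive")
  expect_equal(lab$cluster_labels[2], "negative")
  expect_error(label_clusters(fit, c(labels[-1], NA)), "label")
})

test_that("grid search returns the argmin-BIC combination with its table", {
  g <- make_gaussian_fixture(K = 2, m = 2, separation = 8,
                             n_per_cluster = 25, seed = 19)
  gs <- dpgmm_grid_search(g$x, alphas = c(1, 10), iteration_counts = c(5, 20),
                          seed = 19)
  expect_equal(nrow(gs$table), 4)
  expect_equal(gs$best$bic, min(gs$table$bic))
  expect_equal(dpgmm_bic(gs$best_model, g$x), gs$best$bic)
  expect_error(dpgmm_grid_search(g$x, alphas = numeric(0)), "empty")
})
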