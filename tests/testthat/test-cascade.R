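# Nested-blob geometry: two label super-blobs, each containing two
# miRNA-specific sub-blobs; with a tight homogeneity requirement the tree
# must split twice before the leaves are miRNA-pure.
nested_blobs <- function(n_per = 20, seed = 51) {
  set.seed(seed)
  centers <- rbind(c(-10, -3), c(-10, 3), c(10, -3), c(10, 3))
  x <- do.call(rbind, lapply(1:4, function(k) {
    matrix(rnorm(n_per * 2, sd = 0.8), n_per, 2) +
      matrix(centers[k, ], n_per, 2, byrow = TRUE)
  }))
  colnames(x) <- c("f1", "f2")
  fake_features(
    x,
    labels = rep(c("positive", "positive", "negative", "negative"),
                 each = n_per),
    mirna_ids = rep(paste0("mir-", 1:4), each = n_per),
    mrna_ids = paste0("tx-", seq_len(4 * n_per))
  )
}

test_that("cascade configuration rejects invalid controls", {
  expect_error(cascade_config(size_threshold = 0), "size_threshold")
  expect_error(cascade_config(homogeneity = 0), "homogeneity")
  expect_error(cascade_config(homogeneity = 1.2), "homogeneity")
})

test_that("nested miRNA blobs yield a depth >= 2 tree with miRNA-pure leaves", {
  feats <- nested_blobs()
  tree <- build_cascade(feats,
                        cascade_config(size_threshold = 5, homogeneity = 1.0,
                                       alpha = 1, n_iterations = 30, seed = 5))
  nodes <- cascade_nodes(tree)
  expect_gte(max(nodes$depth), 2)
  leaves <- nodes[nodes$status == "leaf_homogeneous_mirna", ]
  expect_gte(nrow(leaves), 4)
  expect_true(all(leaves$mirna_homogeneity == 1))
  prof <- homogeneity_profile(tree, c(0.5, 0.8, 1.0))
  expect_true(all(prof$fraction == 1))
})

test_that("leaves plus excluded nodes partition the training set", {
  feats <- nested_blobs(n_per = 15, seed = 53)
  tree <- build_cascade(feats,
                        cascade_config(size_threshold = 5, alpha = 1,
                                       n_iterations = 20, seed = 7))
  members <- list()
  walk <- function(node) {
    if (node$status == "internal") {
      for (ch in node$children) walk(ch)
    } else {
      members[[length(members) + 1L]] <<- node$members
    }
  }
  walk(tree$root)
  flat <- sort(unlist(members))
  expect_equal(flat, seq_len(60))   # no loss, no duplication
})

test_that("every terminal node satisfies its recorded stopping condition", {
  feats <- nested_blobs(n_per = 25, seed = 57)
  cfg <- cascade_config(size_threshold = 8, homogeneity = 1.0, max_depth = 3,
                        alpha = 1, n_iterations = 20, seed = 9)
  tree <- build_cascade(feats, cfg)
  nodes <- cascade_nodes(tree)
  expect_lte(max(nodes$depth), cfg$max_depth)
  for (i in seq_len(nrow(nodes))) {
    st <- nodes$status[i]
    if (st == "leaf_homogeneous_mirna") expect_gte(nodes$mirna_homogeneity[i], 1)
    if (st == "leaf_homogeneous_mrna") expect_gte(nodes$mrna_homogeneity[i], 1)
    if (st %in% c("leaf_small", "excluded")) {
      expect_lte(nodes$n[i], cfg$size_threshold)
    }
    if (st == "leaf_maxdepth") expect_equal(nodes$depth[i], cfg$max_depth)
    if (st == "internal") expect_gte(nodes$n_children[i], 2)
    if (st %in% c("excluded", "leaf_converged")) {
      expect_equal(nodes$n_children[i], 0)
    }
  }
})

test_that("a mixed cluster of exactly the size threshold is not re-split", {
  # one tight mixed blob of exactly 30 points next to a large separable one
  set.seed(61)
  x <- rbind(
    matrix(rnorm(30 * 2, sd = 0.5), 30, 2) +
      matrix(c(12, 0), 30, 2, byrow = TRUE),
    matrix(rnorm(60 * 2, sd = 0.8), 60, 2) +
      matrix(c(-12, 0), 60, 2, byrow = TRUE),
    matrix(rnorm(60 * 2, sd = 0.8), 60, 2)
  )
  colnames(x) <- c("f1", "f2")
  feats <- fake_features(
    x,
    labels = c(rep(c("positive", "negative"), 15),
               rep("positive", 60), rep("negative", 60)),
    mirna_ids = c(rep(c("mA", "mB"), 15), rep(c("mC", "mD"), each = 60)),
    mrna_ids = paste0("tx-", 1:150)
  )
  tree <- build_cascade(feats,
                        cascade_config(size_threshold = 30, alpha = 1,
                                       n_iterations = 30, seed = 11))
  nodes <- cascade_nodes(tree)
  sized <- nodes[nodes$n == 30 & nodes$depth > 0, ]
  expect_gte(nrow(sized), 1)
  expect_true(all(sized$n_children == 0))
  expect_true(all(sized$status %in% c("excluded", "leaf_small",
                                      "leaf_homogeneous_mirna",
                                      "leaf_homogeneous_mrna")))
})

test_that("classification descends by argmax and is self-consistent", {
  feats <- nested_blobs()
  std <- feats
  tree <- build_cascade(std, cascade_config(size_threshold = 5, alpha = 1,
                                            n_iterations = 30, seed = 5))
  calls <- classify_interactions(std, tree, level = "leaf", seed = 1)
  # training points land in their own training leaf on this separable fixture
  nodes <- cascade_nodes(tree)
  leaf_of <- rep(NA_character_, nrow(feats))
  walk <- function(node) {
    if (node$status == "internal") {
      for (ch in node$children) walk(ch)
    } else {
      leaf_of[node$members] <<- node$node_id
    }
  }
  walk(tree$root)
  expect_equal(calls$leaf_node, leaf_of)
  expect_true(all(calls$z > 0 & calls$z <= 1))
  # root-level call shares the first path element
  roots <- classify_interactions(std, tree, level = "root", seed = 1)
  first_leaf <- vapply(calls$path, function(p) p[[1]]$cluster_id, integer(1))
  first_root <- vapply(roots$path, function(p) p[[1]]$cluster_id, integer(1))
  expect_equal(first_root, first_leaf)
  expect_equal(vapply(roots$path, length, integer(1)), rep(1L, nrow(feats)))
})

test_that("interaction confidence is the bounded product of its factors", {
  expect_equal(interaction_confidence(0.8, 0.9), 0.72)
  expect_equal(interaction_confidence(1, 1), 1)
  expect_equal(interaction_confidence(0.5, 0), 0)
  expect_error(interaction_confidence(1.2, 0.5), "z")
  expect_error(interaction_confidence(0.5, -0.1), "c_k")
  # monotone in each argument
  z <- seq(0, 1, 0.25)
  expect_true(all(diff(interaction_confidence(z, 0.7)) >= 0))
  expect_true(all(diff(interaction_confidence(0.7, z)) >= 0))
})

test_that("homogeneity profile is monotone non-increasing in the threshold", {
  feats <- nested_blobs(n_per = 15, seed = 63)
  tree <- build_cascade(feats,
                        cascade_config(size_threshold = 5, alpha = 1,
                                       n_iterations = 20, seed = 13))
  prof <- homogeneity_profile(tree, thresholds = c(0, 0.5, 0.8, 0.9, 1))
  expect_true(all(diff(prof$n_homogeneous) <= 0))
  expect_equal(prof$n_homogeneous[1], prof$n_positive_leaves[1])
})

test_that("probes reaching an excluded node get zero confidence", {
  # construct: large separable blobs plus a small mixed clump that the
  # size rule excludes
  set.seed(67)
  x <- rbind(matrix(rnorm(80, -8), 40, 2), matrix(rnorm(80, 8), 40, 2),
             matrix(rnorm(12, 0, 0.3), 6, 2))
  colnames(x) <- c("f1", "f2")
  feats <- fake_features(
    x,
    labels = c(rep("positive", 40), rep("negative", 40),
               rep(c("positive", "negative"), 3)),
    mirna_ids = c(rep("mA", 40), rep("mB", 40), rep(c("mC", "mD"), 3)),
    mrna_ids = paste0("tx-", 1:86)
  )
  std <- feats
  tree <- build_cascade(std, cascade_config(size_threshold = 10, alpha = 1,
                                            n_iterations = 30, seed = 15))
  nodes <- cascade_nodes(tree)
  if (any(nodes$status == "excluded")) {
    calls <- classify_interactions(std, tree, level = "leaf")
    hit <- calls$leaf_status == "excluded"
    expect_true(any(hit))
    expect_true(all(calls$ic[hit] == 0))
  } else {
    succeed("no excluded node formed under this seed")
  }
})
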