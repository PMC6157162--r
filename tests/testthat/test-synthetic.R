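test_that("make_world plants the promised number of positive sites", {
  w <- make_world(n_mirnas = 5, n_transcripts = 20, sites_per_pair = 2,
                  seed = 11)
  expect_equal(nrow(w$interactions), 5 * 20 * 2)
  expect_equal(nrow(w$mirnas), 5)
  expect_equal(nrow(w$transcripts), 20)
  expect_true(all(w$interactions$label == "positive"))
  expect_true(all(w$interactions$site_end <=
                    w$transcripts$length[match(w$interactions$transcript_id,
                                               w$transcripts$id)]))
  # planted site sequence matches the transcript at its coordinates
  for (i in sample(nrow(w$interactions), 20)) {
    tx <- w$transcripts$residues[w$transcripts$id ==
                                   w$interactions$transcript_id[i]]
    expect_equal(substr(tx, w$interactions$site_start[i] + 1,
                        w$interactions$site_end[i]),
                 w$interactions$site_seq[i])
  }
})

test_that("every planted site is fully seed-complementary to its miRNA", {
  w <- make_world(n_mirnas = 3, n_transcripts = 5, sites_per_pair = 2,
                  seed = 13)
  mir <- setNames(w$mirnas$residues, w$mirnas$id)
  for (i in seq_len(nrow(w$interactions))) {
    pc <- seed_pairing_counts(mir[[w$interactions$mirna_id[i]]],
                              w$interactions$site_seq[i])
    expect_equal(pc$seed_pairs, 7L)
    expect_equal(pc$pairs_13_16, 4L)
  }
})

test_that("worlds are byte-identical under a fixed seed", {
  w1 <- make_world(n_mirnas = 3, n_transcripts = 4, seed = 17,
                   n_decoy_mirnas = 2)
  w2 <- make_world(n_mirnas = 3, n_transcripts = 4, seed = 17,
                   n_decoy_mirnas = 2)
  expect_identical(w1, w2)
  fa1 <- withr::local_tempfile(fileext = ".fa")
  fa2 <- withr::local_tempfile(fileext = ".fa")
  write_fasta(w1$transcripts, fa1)
  write_fasta(w2$transcripts, fa2)
  expect_identical(readLines(fa1), readLines(fa2))
  w3 <- make_world(n_mirnas = 3, n_transcripts = 4, seed = 18,
                   n_decoy_mirnas = 2)
  expect_false(identical(w1$transcripts$residues, w3$transcripts$residues))
})

test_that("a too-dense site layout is rejected with a clear error", {
  expect_error(
    make_world(n_mirnas = 6, n_transcripts = 2, sites_per_pair = 3,
               transcript_length = c(100, 120), seed = 1),
    "too short")
})

test_that("Gaussian fixtures are well separated by construction", {
  g <- make_gaussian_fixture(K = 3, m = 2, separation = 10,
                             n_per_cluster = 100, seed = 3)
  expect_equal(dim(g$x), c(300, 2))
  expect_equal(as.vector(table(g$labels)), rep(100L, 3))
  # silhouette of the true labeling (hand-rolled): strongly positive
  d <- as.matrix(dist(g$x))
  sil <- vapply(seq_len(300), function(i) {
    a <- mean(d[i, g$labels == g$labels[i]][-1])
    b <- min(vapply(setdiff(1:3, g$labels[i]),
                    function(k) mean(d[i, g$labels == k]), numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
  expect_gt(mean(sil), 0.8)

  g1 <- make_gaussian_fixture(K = 1, m = 2, seed = 5)
  expect_equal(unique(g1$labels), 1L)
  expect_identical(make_gaussian_fixture(K = 2, seed = 9),
                   make_gaussian_fixture(K = 2, seed = 9))
})
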