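test_that("sliding windows enumerate L - k + 1 sites in coordinate order", {
  tx <- tibble::tibble(id = "t1", residues = rand_rna(25))
  win <- slide_windows(tx, k = 22)
  expect_equal(nrow(win), 4)
  expect_equal(win$start, 0:3)
  expect_equal(win$end, win$start + 22)
  expect_equal(win$site_seq, substring(tx$residues, 1:4, 22:25))

  expect_equal(nrow(slide_windows(tibble::tibble(id = "t", residues = rand_rna(22)), 22)), 1)
  expect_equal(nrow(slide_windows(tibble::tibble(id = "t", residues = rand_rna(21)), 22)), 0)
})

make_negative_world <- function(seed = 101) {
  set.seed(seed)
  make_world(n_mirnas = 3, n_transcripts = 6, sites_per_pair = 1,
             transcript_length = c(150, 200), seed = seed,
             n_decoy_mirnas = 2, n_decoy_transcripts = 3)
}

test_that("tier-1 negatives live on reported pairs off the true sites", {
  w <- make_negative_world()
  neg <- generate_tier(1, w$interactions, w$mirnas, w$transcripts,
                       n_samples = 40, seed = 7)
  expect_true(all(neg$label == "negative"))
  expect_true(all(neg$tier == 1L))
  pos_pairs <- unique(paste(w$interactions$mirna_id,
                            w$interactions$transcript_id))
  expect_true(all(paste(neg$mirna_id, neg$transcript_id) %in% pos_pairs))
  # no window overlaps a true site of its own pair by even 1 nt
  for (i in seq_len(nrow(neg))) {
    hits <- w$interactions[w$interactions$mirna_id == neg$mirna_id[i] &
                             w$interactions$transcript_id == neg$transcript_id[i], ]
    expect_true(all(neg$site_end[i] <= hits$site_start |
                      neg$site_start[i] >= hits$site_end))
  }
})

test_that("tier signatures partition the id space as designed", {
  w <- make_negative_world()
  rep_m <- unique(w$interactions$mirna_id)
  rep_t <- unique(w$interactions$transcript_id)
  t2 <- generate_tier(2, w$interactions, w$mirnas, w$transcripts,
                      n_samples = 30, seed = 7)
  expect_true(all(t2$mirna_id %in% rep_m))
  expect_true(!any(t2$transcript_id %in% rep_t))
  t3 <- generate_tier(3, w$interactions, w$mirnas, w$transcripts,
                      n_samples = 30, seed = 7)
  expect_true(!any(t3$mirna_id %in% rep_m))
  expect_true(all(t3$transcript_id %in% rep_t))
  t4 <- generate_tier(4, w$interactions, w$mirnas, w$transcripts,
                      n_samples = 30, seed = 7)
  expect_true(!any(t4$mirna_id %in% rep_m))
  expect_true(!any(t4$transcript_id %in% rep_t))
})

test_that("negative sampling is exact, unique and seed-reproducible", {
  w <- make_negative_world()
  a <- generate_negative_set(w$interactions, w$mirnas, w$transcripts,
                             tiers = 1:4, n_per_tier = 25, seed = 13)
  b <- generate_negative_set(w$interactions, w$mirnas, w$transcripts,
                             tiers = 1:4, n_per_tier = 25, seed = 13)
  expect_identical(a, b)
  expect_equal(unname(table(a$tier)), rep(25L, 4), ignore_attr = TRUE)
  triple <- paste(a$mirna_id, a$transcript_id, a$site_start)
  expect_equal(anyDuplicated(triple), 0)
  c2 <- generate_negative_set(w$interactions, w$mirnas, w$transcripts,
                              tiers = 1, n_per_tier = 25, seed = 14)
  expect_false(identical(a[a$tier == 1, ], c2))
})

test_that("tiers needing unreported ids fail without decoys, and exhaustion warns", {
  w <- make_world(n_mirnas = 2, n_transcripts = 2, sites_per_pair = 1,
                  transcript_length = c(150, 160), seed = 3)
  expect_error(generate_tier(4, w$interactions, w$mirnas, w$transcripts,
                             n_samples = 5, seed = 1), "unreported")
  # a tiny pool cannot supply the requested count
  small <- make_world(n_mirnas = 1, n_transcripts = 1, sites_per_pair = 1,
                      transcript_length = c(60, 60), site_length = 22,
                      seed = 5)
  expect_warning(
    generate_tier(1, small$interactions, small$mirnas, small$transcripts,
                  n_samples = 5000, seed = 1),
    "only")
})
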