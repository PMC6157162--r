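test_that("k-mer frequencies match direct window counts", {
  v <- kmer_frequencies("AAAA", kmax = 1)
  expect_equal(unname(v[c("k1_A", "k1_C", "k1_G", "k1_U")]), c(1, 0, 0, 0))

  # brute-force window-count oracle on ACGU dimers
  v2 <- kmer_frequencies("ACGU", kmax = 2)
  dimers <- substring("ACGU", 1:3, 2:4)
  for (km in c("AA", "AC", "CG", "GU", "UU")) {
    expect_equal(unname(v2[paste0("k2_", km)]), sum(dimers == km) / 3)
  }
  expect_equal(sum(v2[grepl("^k2_", names(v2))] > 0), 3)

  # degenerate L < k: the whole block is zero
  v3 <- kmer_frequencies("ACG", kmax = 4)
  expect_equal(sum(v3[grepl("^k4_", names(v3))]), 0)
  expect_equal(length(v3), 4 + 16 + 64 + 256)
})

test_that("each k-mer block of a long-enough sequence sums to 1", {
  set.seed(11)
  for (rep in 1:20) {
    s <- rand_rna(sample(4:30, 1))
    v <- kmer_frequencies(s, kmax = 4)
    for (k in 1:4) {
      block <- v[grepl(paste0("^k", k, "_"), names(v))]
      if (nchar(s) >= k) expect_equal(sum(block), 1, tolerance = 1e-12)
    }
  }
})

test_that("seed pairing counts follow the antiparallel anchored register", {
  # positions 2-8 fully Watson-Crick complementary
  mirna <- paste0("A", "GAGGUAG", rand_rna(0), "UACCUCAAGAUGGU")
  site_rev <- paste0("U", "CUCCAUC", "XXXXXXXXXXXXXX")
  site <- paste(rev(strsplit(gsub("X", "A", site_rev), "")[[1]]), collapse = "")
  pc <- seed_pairing_counts(mirna, site)
  expect_equal(pc$seed_pairs, 7L)

  expect_equal(seed_pairing_counts("AAAAAAAA", "AAAAAAAA")$seed_pairs, 0L)

  pc2 <- seed_pairing_counts("UUUUUUUU", "AAAAAAAA")
  expect_equal(pc2$seed_pairs, 7L)
  expect_equal(pc2$total_pairs, 8L)

  expect_error(seed_pairing_counts("UUUUUUU", "AAAAAAAA"), "8")
})

test_that("AU content is a simple fraction with an empty-input convention", {
  expect_equal(au_content("AUAU"), 1)
  expect_equal(au_content("GCGC"), 0)
  expect_equal(au_content("AUGC"), 0.5)
  expect_equal(au_content(""), 0)
})

test_that("positional features place sites within the transcript", {
  p <- positional_features(0, 22, 44)
  expect_equal(p$relative_position, 0.25)
  expect_equal(p$distance_from_center, 0.25)
  expect_equal(p$site_length, 22)

  p2 <- positional_features(39, 61, 100)   # centred site
  expect_equal(p2$distance_from_center, 0)

  p3 <- positional_features(78, 100, 100)
  expect_equal(p3$relative_position, 0.89)
  expect_equal(p3$distance_from_center, 0.39)

  expect_error(positional_features(10, 10, 100), "invalid")
  expect_error(positional_features(90, 101, 100), "invalid")
})

test_that("builtin structure engine reproduces worked maximum pairings", {
  s <- structure_features("GGGAAACCC", engine = "builtin")
  expect_equal(s$mfe_proxy, -3)
  expect_equal(s$open_degree, 3 / 9)
  expect_equal(s$paired_fraction, 6 / 9)

  s2 <- structure_features("AAAA")
  expect_equal(s2$mfe_proxy, 0)
  expect_equal(s2$open_degree, 1)

  # min hairpin loop 3: no pair can form in GCGC
  s3 <- structure_features("GCGC")
  expect_equal(s3$mfe_proxy, 0)
})

test_that("an absent external structure engine is an explicit error", {
  expect_error(
    structure_features("GGGAAACCC", engine = "external",
                       external_cmd = "no-such-folder-binary"),
    "not found")
})

test_that("external structure engine parses a thermodynamic folder", {
  skip_if(Sys.which("RNAfold") == "", "RNAfold not on PATH")
  s <- structure_features(strrep("GC", 20), engine = "external")
  expect_lt(s$mfe_proxy, 0)
  expect_true(s$open_degree >= 0 && s$open_degree <= 1)
  expect_equal(s$open_degree + s$paired_fraction, 1)
})

test_that("feature matrices are registry-shaped, deterministic and handle edges", {
  w <- make_world(n_mirnas = 2, n_transcripts = 2, sites_per_pair = 1,
                  transcript_length = c(120, 140), seed = 17)
  # add a site flush against the transcript start: truncated flank, no error
  tx1 <- w$transcripts$residues[1]
  edge <- tibble::tibble(mirna_id = w$mirnas$id[1],
                         transcript_id = w$transcripts$id[1],
                         site_start = 0L, site_end = 22L,
                         site_seq = substr(tx1, 1, 22),
                         label = "negative", tier = NA_integer_, source = "x")
  ints <- dplyr::bind_rows(w$interactions, edge)
  fm <- build_feature_matrix(ints, w$mirnas, w$transcripts)
  registry <- feature_registry(feature_config())
  expect_equal(attr(fm, "feature_names"), registry)
  expect_equal(ncol(fm), length(registry) + 5)
  expect_true(all(is.finite(as.matrix(fm[registry]))))
  expect_equal(fm$au_flank_up[nrow(fm)], 0)   # no upstream flank at the edge

  fm2 <- build_feature_matrix(ints, w$mirnas, w$transcripts)
  expect_identical(fm, fm2)

  missing <- dplyr::mutate(edge, mirna_id = "mir-xyz")
  expect_error(build_feature_matrix(missing, w$mirnas, w$transcripts),
               "mir-xyz")
})

test_that("standardization yields z-scores, flags constants, and round-trips", {
  x <- cbind(a = c(1, 2, 3), b = c(5, 5, 5), c = c(0, 2, 10))
  feats <- fake_features(x, rep("positive", 3), rep("m", 3), paste0("t", 1:3))
  std <- standardize_features(feats)
  expect_equal(std$a, (c(1, 2, 3) - 2) / sd(c(1, 2, 3)))
  expect_equal(std$b, rep(0, 3))
  params <- attr(std, "standardization")
  expect_true(params$zero_variance[["b"]])

  # probe transformed with stored params equals training-time transform
  probe <- feats[2, ]
  attr(probe, "feature_names") <- colnames(x)
  again <- apply_standardization(probe, params)
  expect_equal(as.numeric(again[1, c("a", "b", "c")]),
               as.numeric(std[2, c("a", "b", "c")]))

  expect_error(standardize_features(feats[1, ]), "n >= 2")
})

test_that("feature-column subsetting keeps attributes consistent", {
  x <- cbind(a = rnorm(5), b = rnorm(5), c = rnorm(5))
  feats <- fake_features(x, rep("positive", 5), rep("m", 5), paste0("t", 1:5))
  sub <- select_feature_columns(feats, c("c", "a"))
  expect_equal(attr(sub, "feature_names"), c("a", "c"))  # registry order
  expect_error(select_feature_columns(feats, "nope"), "unknown feature")
})
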