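# Shared fixtures and independent oracles, built in code at test time.

# Wrap a plain matrix as a feature tibble with metadata columns, so the
# cascade can be exercised on constructed geometries.
fake_features <- function(x, labels, mirna_ids, mrna_ids) {
  colnames(x) <- colnames(x) %||% paste0("f", seq_len(ncol(x)))
  out <- dplyr::bind_cols(
    tibble::tibble(interaction_id = paste0("i", seq_len(nrow(x))),
                   mirna_id = mirna_ids, transcript_id = mrna_ids,
                   label = labels, tier = NA_integer_),
    tibble::as_tibble(x)
  )
  attr(out, "feature_names") <- colnames(x)
  attr(out, "fingerprint") <- "test-fixture"
  # constructed geometries are already in model units: attach an identity
  # standardization so the cascade does not rescale them
  attr(out, "standardization") <- list(
    mean = stats::setNames(rep(0, ncol(x)), colnames(x)),
    sd = stats::setNames(rep(1, ncol(x)), colnames(x)),
    zero_variance = stats::setNames(rep(FALSE, ncol(x)), colnames(x))
  )
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent Smith-Waterman oracle: plain top-down recursion (no wavefront
# fill), memoized on the (i, j) suffix;  enumerates the same path space the
# implementation optimizes over but through a different formulation.
oracle_sw <- function(mirna, site, match = 2, wobble = 1, mismatch = -1,
                      gap = 2) {
  a <- strsplit(mirna, "")[[1]]
  b <- rev(strsplit(site, "")[[1]])
  n <- length(a); m <- length(b)
  pair_score <- function(x, y) {
    if ((x == "A" && y == "U") || (x == "U" && y == "A") ||
        (x == "G" && y == "C") || (x == "C" && y == "G")) return(match)
    if ((x == "G" && y == "U") || (x == "U" && y == "G")) return(wobble)
    mismatch
  }
  memo <- array(NA_real_, c(n + 1, m + 1))
  ending_at <- function(i, j) {           # best alignment ending at (i, j)
    if (i == 0 || j == 0) return(0)
    if (!is.na(memo[i + 1, j + 1])) return(memo[i + 1, j + 1])
    v <- max(0,
             ending_at(i - 1, j - 1) + pair_score(a[i], b[j]),
             ending_at(i - 1, j) - gap,
             ending_at(i, j - 1) - gap)
    memo[i + 1, j + 1] <<- v
    v
  }
  best <- 0
  for (i in seq_len(n)) for (j in seq_len(m)) best <- max(best, ending_at(i, j))
  best
}

# Independent maximum-base-pairing oracle: exhaustive recursive enumeration
# of all non-crossing structures (no memoization), for sequences <= 12 nt.
oracle_max_pairs <- function(seq, min_loop = 3) {
  x <- strsplit(seq, "")[[1]]
  pairable <- function(p, q) {
    s <- paste0(x[p], x[q])
    s %in% c("AU", "UA", "GC", "CG", "GU", "UG")
  }
  rec <- function(i, j) {
    if (j - i < min_loop + 1) return(0)
    best <- rec(i, j - 1)                    # j unpaired
    for (k in i:(j - min_loop - 1)) {
      if (pairable(k, j)) {
        left <- if (k > i) rec(i, k - 1) else 0
        inner <- if (k + 1 <= j - 1) rec(k + 1, j - 1) else 0
        best <- max(best, left + inner + 1)
      }
    }
    best
  }
  if (length(x) < 2) 0 else rec(1, length(x))
}

# Exhaustive set-partition enumeration (restricted-growth strings).
all_partitions <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in all_partitions(n - 1)) {
    for (k in seq_len(max(p) + 1L)) out[[length(out) + 1L]] <- c(p, k)
  }
  out
}

# Adjusted Rand index from the contingency-table closed form.
oracle_ari <- function(a, b) {
  tab <- table(a, b)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  nc2 <- choose(sum(tab), 2)
  expected <- si * sj / nc2
  (sij - expected) / ((si + sj) / 2 - expected)
}

rand_rna <- function(L) paste(sample(c("A", "C", "G", "U"), L, replace = TRUE),
                              collapse = "")

# The end-to-end study world: built once per test run (training the
# cascade takes ~1 min) and reused by the acceptance tests.
e2e_cache <- new.env(parent = emptyenv())
e2e_fixture <- function(seed = 3L) {
  key <- paste0("s", seed)
  if (!is.null(e2e_cache[[key]])) return(e2e_cache[[key]])
  w <- make_world(n_mirnas = 4, n_transcripts = 12, sites_per_pair = 2,
                  seed = seed, n_decoy_mirnas = 3, n_decoy_transcripts = 5)
  neg <- generate_negative_set(w$interactions, w$mirnas, w$transcripts,
                               tiers = 1:4, n_per_tier = 25, seed = seed)
  all_int <- dplyr::bind_rows(w$interactions, neg)
  sp <- split_interactions(all_int, 0.25, seed = seed)
  cc <- cascade_config(size_threshold = 15, grid = "all",
                       alphas = c(1, 10, 30, 60, 100),
                       iteration_counts = 30L, seed = seed)
  pipe <- train_pipeline(sp$train, w$mirnas, w$transcripts, cascade = cc,
                         seed = seed)
  fx <- list(world = w, negatives = neg, split = sp, pipeline = pipe)
  e2e_cache[[key]] <- fx
  fx
}
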