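# Self-contained synthetic test worlds.  The planted signal is seed
# complementarity — each positive site carries the reverse complement of
# the miRNA's seed region (bases 2-8 from the 5' end), optionally plus a
# 3' supplementary block (bases 13-16) — because seed pairing is the
# primary binding determinant.  The remaining site positions pair with
# probability `extra_pairing`, emulating the extensive non-seed duplexes
# seen in chimeric-read data; transcript background is uniform-random, so
# a model cannot separate classes on composition alone.

#' Generate a synthetic miRNA/transcript world with planted interactions
#'
#' Every (miRNA, transcript) pair receives `sites_per_pair` planted
#' positive sites at disjoint, recorded positions.  Decoy sequences (never
#' appearing in a positive interaction) provide the "unreported" pools the
#' tiered negative generator needs.
#'
#' @param n_mirnas,n_transcripts Numbers of (reported) sequences.
#' @param mirna_length miRNA length in nt (default 22).
#' @param transcript_length Length range (min, max) for transcripts.
#' @param sites_per_pair Planted sites per (miRNA, transcript) pair.
#' @param site_length Planted site length (default 22).
#' @param supplementary Also plant the 13-16 complementary block.
#' @param extra_pairing Probability that each site position outside the
#'   planted blocks is complementary to its miRNA counterpart (extensive
#'   duplex pairing; default 0.5).
#' @param n_decoy_mirnas,n_decoy_transcripts Extra sequences without any
#'   planted site.
#' @param seed Integer seed; output is deterministic.
#' @return A list with `mirnas`, `transcripts` (sequence tibbles) and
#'   `interactions` (positive interaction tibble).
#' @export
make_world <- function(n_mirnas = 5L, n_transcripts = 20L, mirna_length = 22L,
                       transcript_length = c(300L, 500L), sites_per_pair = 2L,
                       site_length = 22L, supplementary = TRUE,
                       extra_pairing = 0.5,
                       n_decoy_mirnas = 0L, n_decoy_transcripts = 0L,
                       seed = 1L) {
  stopifnot(n_mirnas >= 1L, n_transcripts >= 1L, sites_per_pair >= 1L,
            mirna_length >= 16L, site_length >= 16L,
            length(transcript_length) == 2L)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(derive_seed(seed, "world"))

  rand_seq <- function(L) paste(sample(RNA_BASES, L, replace = TRUE),
                                collapse = "")
  mir_ids <- sprintf("mir-%03d", seq_len(n_mirnas + n_decoy_mirnas))
  mirnas <- tibble::tibble(
    id = mir_ids, kind = "miRNA",
    residues = vapply(mir_ids, function(i) rand_seq(mirna_length), ""),
    length = mirna_length
  )
  tx_ids <- sprintf("tx-%03d", seq_len(n_transcripts + n_decoy_transcripts))
  len_range <- transcript_length[1L]:transcript_length[2L]
  tx_len <- len_range[sample.int(length(len_range), length(tx_ids),
                                 replace = TRUE)]
  tx_res <- vapply(seq_along(tx_ids), function(i) rand_seq(tx_len[i]), "")

  # a planted site pairing the miRNA antiparallel: reversed-site position r
  # must complement miRNA position r, i.e. site[L+1-r] = comp(mirna[r])
  plant_site <- function(mirna) {
    site <- strsplit(rand_seq(site_length), "")[[1L]]
    mir <- strsplit(mirna, "")[[1L]]
    planted <- 2:8
    if (supplementary) planted <- c(planted, 13:16)
    for (r in seq_len(min(length(mir), site_length))) {
      if (r %in% planted || stats::runif(1L) < extra_pairing) {
        site[site_length + 1L - r] <- RNA_COMPLEMENT[[mir[r]]]
      }
    }
    paste(site, collapse = "")
  }

  inter <- list()
  n_slots <- n_mirnas * sites_per_pair
  for (j in seq_len(n_transcripts)) {
    L <- tx_len[j]
    slot <- L %/% n_slots
    if (slot < site_length) {
      stop(sprintf(
        "transcript %s (length %d) too short for %d sites of %d nt",
        tx_ids[j], L, n_slots, site_length), call. = FALSE)
    }
    slot_order <- sample.int(n_slots)
    s <- 0L
    for (i in seq_len(n_mirnas)) {
      for (rep_i in seq_len(sites_per_pair)) {
        s <- s + 1L
        slot_i <- slot_order[s]
        off <- sample.int(slot - site_length + 1L, 1L) - 1L
        start <- (slot_i - 1L) * slot + off
        site <- plant_site(mirnas$residues[i])
        tx_res[j] <- paste0(substr(tx_res[j], 1L, start), site,
                            substr(tx_res[j], start + site_length + 1L, L))
        inter[[length(inter) + 1L]] <- tibble::tibble(
          mirna_id = mir_ids[i], transcript_id = tx_ids[j],
          site_start = start, site_end = start + site_length,
          site_seq = site, label = "positive", tier = NA_integer_,
          source = "planted")
      }
    }
  }
  transcripts <- tibble::tibble(id = tx_ids, kind = "transcript",
                                residues = tx_res, length = nchar(tx_res))
  list(mirnas = mirnas, transcripts = transcripts,
       interactions = dplyr::bind_rows(inter))
}

#' Generate an isotropic Gaussian blob fixture for clustering tests
#'
#' `K` blobs with unit within-cluster standard deviation, means laid out on
#' a line centred at the origin with neighbouring means `separation` apart
#' (so pairwise mean distances are at least `separation` standard
#' deviations, and the layout is compatible with standardized data).
#'
#' @param K Number of blobs.
#' @param m Dimensionality.
#' @param separation Distance between neighbouring means, in within-cluster
#'   standard deviations (> 0).
#' @param n_per_cluster Points per blob.
#' @param seed Integer seed.
#' @return A list with `x` (numeric matrix) and `labels` (integer vector).
#' @export
make_gaussian_fixture <- function(K = 3L, m = 2L, separation = 10,
                                  n_per_cluster = 100L, seed = 1L) {
  stopifnot(K >= 1L, m >= 1L, separation > 0, n_per_cluster >= 1L)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(derive_seed(seed, "gaussians"))
  centers <- matrix(0, K, m)
  centers[, 1L] <- separation * (seq_len(K) - (K + 1) / 2)
  x <- do.call(rbind, lapply(seq_len(K), function(k) {
    matrix(stats::rnorm(n_per_cluster * m), n_per_cluster, m) +
      matrix(centers[k, ], n_per_cluster, m, byrow = TRUE)
  }))
  colnames(x) <- paste0("f", seq_len(m))
  list(x = x, labels = rep(seq_len(K), each = n_per_cluster),
       centers = centers)
}
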