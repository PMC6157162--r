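# Tiered negative-set synthesis.  Candidate false sites come from a k-mer
# window slid across transcript sequences; the four tiers stratify the
# negative space by how far the (miRNA, transcript) pair is from the
# reported interactome:
#   tier 1: reported pair, window not overlapping any of its true sites
#   tier 2: reported miRNA x unreported transcript
#   tier 3: unreported miRNA x reported transcript
#   tier 4: unreported miRNA x unreported transcript

#' Sliding windows over a transcript
#'
#' @param transcript A one-row sequence tibble (from [read_fasta()]) or a
#'   list with `id` and `residues`.
#' @param k Window length.
#' @return A tibble with `transcript_id`, `start`, `end` (0-based
#'   half-open) and `site_seq`; exactly `L - k + 1` rows, or zero rows when
#'   the transcript is shorter than `k`.
#' @export
slide_windows <- function(transcript, k = 22L) {
  stopifnot(k >= 8L)
  res <- transcript$residues
  id <- transcript$id
  stopifnot(length(res) == 1L)
  L <- nchar(res)
  if (L < k) {
    return(tibble::tibble(transcript_id = character(0), start = integer(0),
                          end = integer(0), site_seq = character(0)))
  }
  starts <- 0L:(L - k)
  tibble::tibble(transcript_id = id, start = starts, end = starts + k,
                 site_seq = substring(res, starts + 1L, starts + k))
}

#' Synthesize one tier of negative interactions
#'
#' Sampling is two-stage — a (miRNA, transcript) pair is drawn uniformly,
#' then a window on that transcript — so a transcriptome's windows never
#' need to be materialized at once; this makes sampling uniform over pairs
#' (an approximation to uniformity over windows).  Draws are without
#' replacement on (miRNA, transcript, start) triples; if the tier cannot
#' supply `n_samples` unique records, all available ones are returned with
#' a warning.
#'
#' @param tier Tier 1-4 (see module header).
#' @param positives Tibble of positive interactions.
#' @param mirnas,transcripts Sequence tibbles from [read_fasta()]; ids
#'   appearing in `positives` are the "reported" pools, the rest are
#'   "unreported".
#' @param n_samples Number of negatives to draw (default 8000).
#' @param window_k Window length (default 22).
#' @param min_gap Minimum distance (nt) between a tier-1 window and any
#'   true site of the same pair; 0 means any non-overlapping window.
#' @param seed Integer seed; output is reproducible bit-for-bit.
#' @return A tibble of negative interactions with `tier` set.
#' @export
generate_tier <- function(tier, positives, mirnas, transcripts,
                          n_samples = 8000L, window_k = 22L, min_gap = 0L,
                          seed = 1L) {
  stopifnot(tier %in% 1:4, window_k >= 8L, n_samples >= 1L)
  positives <- validate_interactions(positives)
  rep_mirnas <- unique(positives$mirna_id)
  rep_tx <- unique(positives$transcript_id)
  unrep_mirnas <- setdiff(mirnas$id, rep_mirnas)
  unrep_tx <- setdiff(transcripts$id, rep_tx)
  tx_seq <- stats::setNames(transcripts$residues, transcripts$id)
  tx_len <- stats::setNames(nchar(transcripts$residues), transcripts$id)

  mirna_pool <- if (tier %in% c(1L, 2L)) rep_mirnas else unrep_mirnas
  tx_pool <- if (tier %in% c(1L, 3L)) rep_tx else unrep_tx
  if (tier %in% c(3L, 4L) && length(mirna_pool) == 0L) {
    stop("tier ", tier, " needs unreported miRNAs but none are available",
         call. = FALSE)
  }
  if (tier %in% c(2L, 4L) && length(tx_pool) == 0L) {
    stop("tier ", tier, " needs unreported transcripts but none are available",
         call. = FALSE)
  }
  missing_tx <- setdiff(tx_pool, names(tx_seq))
  if (length(missing_tx) > 0L) {
    stop("no sequence for transcript(s): ",
         paste(utils::head(missing_tx, 3L), collapse = ", "), call. = FALSE)
  }

  # candidate pair list
  if (tier == 1L) {
    pairs <- dplyr::distinct(positives, .data$mirna_id, .data$transcript_id)
  } else {
    pairs <- tidyr::expand_grid(mirna_id = mirna_pool, transcript_id = tx_pool)
  }
  pairs <- dplyr::arrange(pairs, .data$mirna_id, .data$transcript_id)

  # lazily computed valid window starts per pair (tier 1 excludes windows
  # within min_gap of a true site of that pair)
  starts_cache <- vector("list", nrow(pairs))
  valid_starts <- function(p) {
    if (!is.null(starts_cache[[p]])) return(starts_cache[[p]])
    txid <- pairs$transcript_id[p]
    L <- tx_len[[txid]]
    if (L < window_k) {
      starts_cache[[p]] <<- integer(0)
      return(integer(0))
    }
    s <- 0L:(L - window_k)
    if (tier == 1L) {
      hit <- positives[positives$mirna_id == pairs$mirna_id[p] &
                         positives$transcript_id == txid &
                         !is.na(positives$site_start), , drop = FALSE]
      for (q in seq_len(nrow(hit))) {
        # keep windows [s, s+k) at distance >= min_gap from [ps, pe)
        s <- s[s + window_k + min_gap <= hit$site_start[q] |
                 s >= hit$site_end[q] + min_gap]
      }
    }
    starts_cache[[p]] <<- s
    s
  }

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(derive_seed(seed, paste0("tier", tier)))

  taken <- new.env(parent = emptyenv())   # "pair_index:start" -> TRUE
  n_taken_pair <- integer(nrow(pairs))
  live <- seq_len(nrow(pairs))            # pairs with capacity left
  out_mirna <- character(0); out_tx <- character(0); out_start <- integer(0)

  while (length(out_start) < n_samples && length(live) > 0L) {
    p <- live[sample.int(length(live), 1L)]
    vs <- valid_starts(p)
    avail <- vs[!vapply(paste0(p, ":", vs), exists, TRUE, envir = taken)]
    if (length(avail) == 0L) {
      live <- setdiff(live, p)
      next
    }
    s <- avail[sample.int(length(avail), 1L)]
    assign(paste0(p, ":", s), TRUE, envir = taken)
    out_mirna <- c(out_mirna, pairs$mirna_id[p])
    out_tx <- c(out_tx, pairs$transcript_id[p])
    out_start <- c(out_start, s)
    if (length(avail) == 1L) live <- setdiff(live, p)
  }
  if (length(out_start) < n_samples) {
    warning(sprintf("tier %d: only %d unique negatives available (requested %d)",
                    tier, length(out_start), n_samples))
  }
  tibble::tibble(
    mirna_id = out_mirna,
    transcript_id = out_tx,
    site_start = out_start,
    site_end = out_start + window_k,
    site_seq = substring(tx_seq[out_tx], out_start + 1L, out_start + window_k),
    label = "negative",
    tier = as.integer(tier),
    source = paste0("synthetic_tier", tier)
  )
}

#' Synthesize the full tiered negative set
#'
#' @inheritParams generate_tier
#' @param tiers Which tiers to generate.
#' @param n_per_tier Negatives per tier.
#' @return A tibble of negatives over all requested tiers.
#' @export
generate_negative_set <- function(positives, mirnas, transcripts,
                                  tiers = 1:4, n_per_tier = 8000L,
                                  window_k = 22L, min_gap = 0L, seed = 1L) {
  purrr::map_dfr(tiers, function(t) {
    generate_tier(t, positives, mirnas, transcripts, n_samples = n_per_tier,
                  window_k = window_k, min_gap = min_gap, seed = seed)
  })
}
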