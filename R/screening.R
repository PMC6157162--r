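# Transcriptome screening: candidate sites are discovered by iterated
# local complementarity alignment with masking, extended by 30 nt on each
# side, featurized with the training-time registry and standardization,
# routed through the cascade tree at leaf level, and ranked by the
# interaction-confidence score.

#' Find candidate binding sites of a miRNA on a transcript
#'
#' The best local complementarity alignment of the miRNA against the
#' (reversed) transcript is found; if its score reaches `min_score`, the
#' aligned span is converted to a candidate site in the canonical
#' antiparallel register — the window whose last base pairs miRNA position
#' 1, one miRNA length long (clamped at the transcript start) — masked,
#' and the search repeats, so candidate sites never overlap.  Extended
#' coordinates are the site plus `flank_width` nt on each side, clamped at
#' the transcript bounds.
#'
#' @param mirna miRNA sequence.
#' @param transcript Transcript sequence.
#' @param scoring An [align_params()].
#' @param min_score Minimum alignment score for a candidate site.
#' @param max_sites Maximum number of sites returned per pair.
#' @param flank_width Extension width in nt.
#' @return A tibble with `site_start`, `site_end`, `ext_start`, `ext_end`
#'   (0-based half-open) and `alignment_score`, sorted by score descending.
#' @export
find_candidate_sites <- function(mirna, transcript, scoring = align_params(),
                                 min_score = 12, max_sites = 10L,
                                 flank_width = 30L) {
  mirna <- normalize_rna(mirna, "mirna")
  transcript <- normalize_rna(transcript, "transcript")
  a <- encode_rna(strsplit(mirna, "")[[1L]])
  b <- encode_rna(rev(strsplit(transcript, "")[[1L]]))
  L <- length(b)
  out <- list()
  n_mir <- length(a)
  tx_code <- rev(b)                       # transcript in original orientation
  seed_idx <- if (n_mir >= 2L) 2L:min(8L, n_mir) else integer(0)
  # anchored Watson-Crick seed pairs of the window ending at e (1-based):
  # miRNA position r pairs transcript position e + 1 - r
  seed_pairs_at <- function(e) {
    tpos <- e + 1L - seed_idx
    ok <- tpos >= 1L & tpos <= L
    sum(PAIRABLE_WC[cbind(a[seed_idx[ok]], tx_code[tpos[ok]])])
  }
  repeat {
    if (length(out) >= max_sites) break
    H <- sw_matrix(a, b, scoring)
    if (max(H) < min_score) break
    tb <- sw_traceback(H, a, b, scoring)
    if (tb$b_end <= tb$b_start) break
    # canonical register: miRNA position 1 pairs the site's last base, so
    # the site end extends past the aligned span by the unaligned miRNA
    # 5' offset; the site is one miRNA length long, clamped at position 0
    span_start <- L - tb$b_end
    span_end <- L - tb$b_start
    register_end <- min(L, span_end + tb$a_start)
    # register refinement: among window ends consistent with the aligned
    # span, prefer the one with the most seed-region pairs (the anchored
    # register the site features assume); ties keep the closest to the
    # alignment-derived register
    cand_e <- max(8L, span_start + 1L):min(L, span_end + n_mir)
    # keep only windows that stay clear of previously emitted sites
    cand_e <- cand_e[vapply(cand_e, function(e) {
      all(tx_code[max(1L, e - n_mir + 1L):e] != 5L)
    }, logical(1))]
    if (length(cand_e) == 0L) {
      site_start <- span_start
      site_end <- span_end
    } else {
      sp <- vapply(cand_e, seed_pairs_at, integer(1))
      best <- cand_e[sp == max(sp)]
      site_end <- best[which.min(abs(best - register_end))]
      site_start <- max(0L, site_end - n_mir)
    }
    out[[length(out) + 1L]] <- tibble::tibble(
      site_start = site_start, site_end = site_end,
      ext_start = max(0L, site_start - flank_width),
      ext_end = min(L, site_end + flank_width),
      alignment_score = tb$score)
    # mask the union of the aligned span and the emitted site
    mask_lo <- min(tb$b_start + 1L, L - site_end + 1L)
    mask_hi <- max(tb$b_end, L - site_start)
    b[mask_lo:mask_hi] <- 5L
    tx_code[(L - mask_hi + 1L):(L - mask_lo + 1L)] <- 5L
  }
  if (length(out) == 0L) {
    return(tibble::tibble(site_start = integer(0), site_end = integer(0),
                          ext_start = integer(0), ext_end = integer(0),
                          alignment_score = numeric(0)))
  }
  dplyr::arrange(dplyr::bind_rows(out), dplyr::desc(.data$alignment_score),
                 .data$site_start)
}

#' Screen miRNA/transcript pairs through a trained cascade tree
#'
#' For every (miRNA, transcript) pair, candidate sites are discovered by
#' iterated local alignment, featurized exactly as at training time (the
#' feature-configuration fingerprint is checked; a mismatch refuses to
#' run), classified at leaf level, and filtered to predictions whose leaf
#' is positive with `ic > ic_min`.
#'
#' @param tree A fitted `cascade_dpgmm`.
#' @param mirnas,transcripts Sequence tibbles from [read_fasta()].
#' @param config The [feature_config()] used at training time.
#' @param min_score,max_sites,ic_min Screening thresholds.
#' @param seed Optional seed for tie-breaks.
#' @return A prediction tibble sorted by `ic` descending with columns
#'   `mirna_id`, `transcript_id`, `site_start`, `site_end`,
#'   `alignment_score`, `leaf_node`, `z`, `dominant_mirna`, `c_k`, `ic`.
#' @export
screen_transcriptome <- function(tree, mirnas, transcripts,
                                 config = feature_config(), min_score = 12,
                                 max_sites = 10L, ic_min = 0, seed = NULL) {
  stopifnot(inherits(tree, "cascade_dpgmm"))
  base_fp <- sub("\\|sel:.*$", "", tree$fingerprint)
  if (!identical(config_fingerprint(config), base_fp)) {
    stop("feature configuration fingerprint does not match the trained model; ",
         "screening must use the training-time feature configuration",
         call. = FALSE)
  }
  cand <- purrr::map_dfr(seq_len(nrow(mirnas)), function(i) {
    purrr::map_dfr(seq_len(nrow(transcripts)), function(j) {
      sites <- find_candidate_sites(mirnas$residues[i], transcripts$residues[j],
                                    scoring = config$scoring,
                                    min_score = min_score,
                                    max_sites = max_sites,
                                    flank_width = config$flank_width)
      # featurization needs at least a seed-sized site
      sites <- sites[sites$site_end - sites$site_start >= 8L, , drop = FALSE]
      if (nrow(sites) == 0L) return(NULL)
      dplyr::mutate(sites, mirna_id = mirnas$id[i],
                    transcript_id = transcripts$id[j], .before = 1L)
    })
  })
  if (nrow(cand) == 0L) {
    return(tibble::tibble(mirna_id = character(0), transcript_id = character(0),
                          site_start = integer(0), site_end = integer(0),
                          alignment_score = numeric(0), leaf_node = character(0),
                          z = numeric(0), dominant_mirna = character(0),
                          c_k = numeric(0), ic = numeric(0)))
  }
  interactions <- tibble::tibble(
    mirna_id = cand$mirna_id, transcript_id = cand$transcript_id,
    site_start = cand$site_start, site_end = cand$site_end,
    site_seq = purrr::pmap_chr(
      list(cand$transcript_id, cand$site_start, cand$site_end),
      function(tx, s, e) {
        substr(transcripts$residues[match(tx, transcripts$id)], s + 1L, e)
      }),
    label = "unknown", tier = NA_integer_, source = "screen"
  )
  feats <- build_feature_matrix(interactions, mirnas, transcripts, config)
  feats <- select_feature_columns(feats, tree$feature_names)
  calls <- classify_interactions(feats, tree, level = "leaf", seed = seed)
  out <- dplyr::bind_cols(
    cand[c("mirna_id", "transcript_id", "site_start", "site_end",
           "alignment_score")],
    calls[c("leaf_node", "predicted_label", "z", "dominant_mirna", "c_k", "ic")]
  )
  out |>
    dplyr::filter(.data$predicted_label == "positive", .data$ic > ic_min) |>
    dplyr::select(-"predicted_label") |>
    dplyr::arrange(dplyr::desc(.data$ic), .data$mirna_id, .data$transcript_id,
                   .data$site_start)
}

#' Per-miRNA and per-transcript regulator statistics
#'
#' @param predictions A prediction tibble from [screen_transcriptome()].
#' @return A list with `targets_per_mirna` and `regulators_per_transcript`
#'   count tibbles plus their means (`mean_targets`, `mean_regulators`);
#'   empty input yields empty tables.
#' @export
regulator_statistics <- function(predictions) {
  pairs <- dplyr::distinct(predictions, .data$mirna_id, .data$transcript_id)
  targets <- dplyr::count(pairs, .data$mirna_id, name = "n_targets")
  regulators <- dplyr::count(pairs, .data$transcript_id, name = "n_regulators")
  list(
    targets_per_mirna = targets,
    regulators_per_transcript = regulators,
    mean_targets = if (nrow(targets) > 0L) mean(targets$n_targets) else NA_real_,
    mean_regulators = if (nrow(regulators) > 0L) mean(regulators$n_regulators) else NA_real_
  )
}
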