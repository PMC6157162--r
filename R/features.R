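# Feature generation: every binding site becomes one row of an
# interaction-by-feature table consumed by the mixture model.

#' Feature-generation configuration
#'
#' Controls the feature registry.  Feature categories mirror what is known
#' to discriminate genuine miRNA binding sites: k-mer composition of both
#' partners, seed-region and whole-duplex pairing counts, the local
#' complementarity alignment score, AU content of the flanking sequence,
#' site position within the transcript, and secondary-structure
#' accessibility of the extended site.
#'
#' @param kmax Largest k for the k-mer frequency blocks (k = 1..kmax).
#' @param flank_width Flank width in nt on each side of the site, used both
#'   for AU-content features and for the structure window.
#' @param scoring [align_params()] used for the alignment-score feature.
#' @param structure_engine `"builtin"` (Nussinov maximum pairing) or
#'   `"external"` (an installed thermodynamic folder, e.g. `RNAfold`).
#' @param min_loop Minimum hairpin loop for the builtin structure engine.
#' @param categories Character vector of feature categories to include;
#'   any subset of `c("kmer", "pairing", "alignment", "au", "positional",
#'   "structure", "length")`.
#' @return A list of class `feature_config`.
#' @export
feature_config <- function(kmax = 4L, flank_width = 30L,
                           scoring = align_params(),
                           structure_engine = c("builtin", "external"),
                           min_loop = 3L,
                           categories = c("kmer", "pairing", "alignment",
                                          "au", "positional", "structure",
                                          "length")) {
  structure_engine <- match.arg(structure_engine)
  known <- c("kmer", "pairing", "alignment", "au", "positional", "structure",
             "length")
  bad <- setdiff(categories, known)
  if (length(bad) > 0L) stop("unknown feature categories: ",
                             paste(bad, collapse = ", "), call. = FALSE)
  structure(list(kmax = as.integer(kmax), flank_width = as.integer(flank_width),
                 scoring = scoring, structure_engine = structure_engine,
                 min_loop = as.integer(min_loop), categories = categories),
            class = "feature_config")
}

all_kmers <- function(k) {
  if (k == 1L) return(RNA_BASES)
  g <- expand.grid(replicate(k, RNA_BASES, simplify = FALSE),
                   stringsAsFactors = FALSE)
  do.call(paste0, rev(g))  # first base most significant: AA, AC, AG, AU, CA, ...
}

#' Feature registry: the fixed, ordered feature-name vector
#'
#' The registry fixes the order and identity of every feature column; every
#' feature matrix built under one configuration has exactly these columns.
#'
#' @param config A [feature_config()].
#' @return Character vector of feature names.
#' @export
feature_registry <- function(config = feature_config()) {
  nm <- character(0)
  if ("kmer" %in% config$categories) {
    for (prefix in c("mir", "site")) {
      for (k in seq_len(config$kmax)) {
        nm <- c(nm, paste0(prefix, "_k", k, "_", all_kmers(k)))
      }
    }
  }
  if ("pairing" %in% config$categories) {
    nm <- c(nm, "seed_pairs", "total_pairs", "pairs_13_16")
  }
  if ("alignment" %in% config$categories) nm <- c(nm, "alignment_score")
  if ("au" %in% config$categories) nm <- c(nm, "au_flank_up", "au_flank_down")
  if ("positional" %in% config$categories) {
    nm <- c(nm, "relative_position", "distance_from_center", "site_length")
  }
  if ("structure" %in% config$categories) {
    nm <- c(nm, "mfe_proxy", "open_degree", "paired_fraction")
  }
  if ("length" %in% config$categories) nm <- c(nm, "mirna_length")
  nm
}

# Short fingerprint of a feature configuration; stored in trained models and
# checked at screening time so features are always built the way the model
# was trained.
config_fingerprint <- function(config) {
  s <- config$scoring
  paste("fc1", config$kmax, config$flank_width, config$structure_engine,
        config$min_loop, paste(sort(config$categories), collapse = "+"),
        s$match, s$wobble, s$mismatch, s$gap, sep = ":")
}

#' k-mer frequency vector of a sequence
#'
#' For each k in 1..`kmax`, the 4^k k-mer counts are divided by the number
#' of windows (L - k + 1), so each block sums to 1; blocks with L < k are
#' all zero.
#'
#' @param seq RNA (or DNA) sequence.
#' @param kmax Largest k.
#' @return Named numeric vector of length sum(4^k).
#' @examples
#' kmer_frequencies("ACGU", kmax = 2)[c("k1_A", "k2_AC")]
#' @export
kmer_frequencies <- function(seq, kmax = 4L) {
  stopifnot(kmax >= 1L)
  seq <- normalize_rna(seq, "seq")
  code <- encode_rna(strsplit(seq, "")[[1L]]) - 1L
  L <- length(code)
  out <- numeric(0)
  for (k in seq_len(kmax)) {
    block <- numeric(4L^k)
    names(block) <- paste0("k", k, "_", all_kmers(k))
    if (L >= k) {
      idx <- 0L
      for (off in 0L:(k - 1L)) {
        idx <- idx * 4L + code[(1L + off):(L - k + 1L + off)]
      }
      tab <- tabulate(idx + 1L, nbins = 4L^k)
      block[] <- tab / (L - k + 1L)
    }
    out <- c(out, block)
  }
  out
}

#' Watson-Crick pairing counts between a miRNA and a site
#'
#' The miRNA (5'->3') is juxtaposed against the reversed site (an
#' antiparallel, ungapped duplex anchored at position 1 of both).
#' `seed_pairs` counts Watson-Crick pairs at miRNA positions 2-8 (the seed
#' region), `total_pairs` over the whole overlap, and `pairs_13_16` at
#' miRNA positions 13-16 (3' supplementary pairing).
#'
#' @param mirna miRNA sequence, length >= 8.
#' @param site_seq Site sequence.
#' @return A one-row tibble with `seed_pairs`, `total_pairs`, `pairs_13_16`.
#' @export
seed_pairing_counts <- function(mirna, site_seq) {
  mirna <- normalize_rna(mirna, "mirna")
  site_seq <- normalize_rna(site_seq, "site_seq")
  if (nchar(mirna) < 8L) {
    stop("miRNA shorter than the 8 nt needed to span a seed region",
         call. = FALSE)
  }
  a <- strsplit(mirna, "")[[1L]]
  b <- rev(strsplit(site_seq, "")[[1L]])
  L <- min(length(a), length(b))
  wc <- is_wc_pair(a[seq_len(L)], b[seq_len(L)])
  count_range <- function(from, to) {
    if (from > L) return(0L)
    sum(wc[from:min(to, L)])
  }
  tibble::tibble(
    seed_pairs = count_range(2L, 8L),
    total_pairs = sum(wc),
    pairs_13_16 = count_range(13L, 16L)
  )
}

#' AU content of a sequence
#'
#' @param flank_seq RNA sequence; may be empty (returns 0).
#' @return Fraction of A and U residues, in `[0, 1]`.
#' @export
au_content <- function(flank_seq) {
  if (is.na(flank_seq) || nchar(flank_seq) == 0L) return(0)
  flank_seq <- normalize_rna(flank_seq, "flank_seq")
  chars <- strsplit(flank_seq, "")[[1L]]
  sum(chars %in% c("A", "U")) / length(chars)
}

#' Positional features of a site within its transcript
#'
#' @param site_start,site_end 0-based half-open site coordinates.
#' @param transcript_length Transcript length.
#' @return One-row tibble with `relative_position` (site midpoint over
#'   transcript length), `distance_from_center` and `site_length`.
#' @export
positional_features <- function(site_start, site_end, transcript_length) {
  if (!(site_start >= 0L && site_start < site_end &&
        site_end <= transcript_length)) {
    stop(sprintf("invalid site coordinates [%s, %s) on transcript of length %s",
                 site_start, site_end, transcript_length), call. = FALSE)
  }
  rel <- ((site_start + site_end) / 2) / transcript_length
  tibble::tibble(relative_position = rel,
                 distance_from_center = abs(rel - 0.5),
                 site_length = site_end - site_start)
}

#' Secondary-structure accessibility of a (flanked) site
#'
#' With the builtin engine, the Nussinov maximum base-pairing structure
#' (Watson-Crick + G:U, minimum hairpin loop `min_loop`) is computed;
#' `mfe_proxy` is the negated pair count, `open_degree` the unpaired
#' fraction (an accessibility proxy) and `paired_fraction` its complement.
#' With the external engine, an installed thermodynamic folder (`RNAfold`)
#' is called through a subprocess contract — sequence on stdin, dot-bracket
#' structure plus free energy on stdout — and `mfe_proxy` is the reported
#' minimum free energy in kcal/mol.
#'
#' @param site_with_flanks Sequence of the site plus flanks.
#' @param engine `"builtin"` or `"external"`.
#' @param min_loop Minimum hairpin loop (builtin engine).
#' @param external_cmd Command for the external folder.
#' @return One-row tibble with `mfe_proxy`, `open_degree`, `paired_fraction`.
#' @export
structure_features <- function(site_with_flanks,
                               engine = c("builtin", "external"),
                               min_loop = 3L, external_cmd = "RNAfold") {
  engine <- match.arg(engine)
  if (engine == "builtin") {
    fold <- nussinov_fold(site_with_flanks, min_loop = min_loop)
    n <- nchar(normalize_rna(site_with_flanks, "site_with_flanks"))
    open_deg <- 1 - sum(fold$paired) / n
    return(tibble::tibble(mfe_proxy = -fold$max_pairs,
                          open_degree = open_deg,
                          paired_fraction = 1 - open_deg))
  }
  if (Sys.which(external_cmd) == "") {
    stop(sprintf("external structure engine '%s' requested but not found on PATH",
                 external_cmd), call. = FALSE)
  }
  seq <- normalize_rna(site_with_flanks, "site_with_flanks")
  out <- suppressWarnings(system2(external_cmd, args = "--noPS", input = seq,
                                  stdout = TRUE, stderr = FALSE))
  if (length(out) < 2L) {
    stop("external structure engine produced no structure line", call. = FALSE)
  }
  line <- out[2L]
  db <- sub("\\s.*$", "", line)
  energy <- as.numeric(sub("^.*\\(\\s*(-?[0-9.]+)\\s*\\)\\s*$", "\\1", line))
  if (is.na(energy)) {
    stop("cannot parse free energy from external engine output: ", line,
         call. = FALSE)
  }
  open_deg <- mean(strsplit(db, "")[[1L]] == ".")
  tibble::tibble(mfe_proxy = energy, open_degree = open_deg,
                 paired_fraction = 1 - open_deg)
}

#' Build the feature matrix for a table of interactions
#'
#' Each interaction row is turned into the registry-ordered feature vector:
#' miRNA and site k-mer blocks, pairing counts, alignment score, AU content
#' of the up/downstream flanks, positional features, structure features of
#' the flank-extended site, and sequence lengths.  Flanks at transcript
#' edges are truncated, not padded.
#'
#' @param interactions Interaction tibble (see [read_interactions()]).
#' @param mirnas,transcripts Sequence tibbles from [read_fasta()].
#' @param config A [feature_config()].
#' @return A tibble with metadata columns (`interaction_id`, `mirna_id`,
#'   `transcript_id`, `label`, `tier`) followed by one numeric column per
#'   registry feature.  The registry fingerprint is stored in attribute
#'   `"fingerprint"`, the feature names in attribute `"feature_names"`.
#' @export
build_feature_matrix <- function(interactions, mirnas, transcripts,
                                 config = feature_config()) {
  interactions <- validate_interactions(interactions)
  registry <- feature_registry(config)
  mir_seq <- stats::setNames(mirnas$residues, mirnas$id)
  tx_seq <- stats::setNames(transcripts$residues, transcripts$id)

  rows <- lapply(seq_len(nrow(interactions)), function(i) {
    build_feature_vector(interactions[i, ], mir_seq, tx_seq, config, registry)
  })
  vals <- do.call(rbind, rows)
  colnames(vals) <- registry
  meta <- tibble::tibble(
    interaction_id = paste(interactions$mirna_id, interactions$transcript_id,
                           dplyr::coalesce(as.character(interactions$site_start), "NA"),
                           sep = "|"),
    mirna_id = interactions$mirna_id,
    transcript_id = interactions$transcript_id,
    label = interactions$label,
    tier = interactions$tier
  )
  out <- dplyr::bind_cols(meta, tibble::as_tibble(vals))
  attr(out, "feature_names") <- registry
  attr(out, "fingerprint") <- config_fingerprint(config)
  out
}

# One interaction -> registry-ordered numeric vector.
build_feature_vector <- function(rec, mir_seq, tx_seq, config, registry) {
  if (!rec$mirna_id %in% names(mir_seq)) {
    stop("no sequence loaded for miRNA id '", rec$mirna_id, "'", call. = FALSE)
  }
  if (!rec$transcript_id %in% names(tx_seq)) {
    stop("no sequence loaded for transcript id '", rec$transcript_id, "'",
         call. = FALSE)
  }
  mirna <- mir_seq[[rec$mirna_id]]
  tx <- tx_seq[[rec$transcript_id]]
  L <- nchar(tx)
  site <- rec$site_seq
  has_coord <- !is.na(rec$site_start) && !is.na(rec$site_end)
  if (has_coord && rec$site_end > L) {
    stop(sprintf("site [%d, %d) outside transcript '%s' (length %d)",
                 rec$site_start, rec$site_end, rec$transcript_id, L),
         call. = FALSE)
  }
  fw <- config$flank_width
  if (has_coord) {
    up <- substr(tx, max(0L, rec$site_start - fw) + 1L, rec$site_start)
    down <- substr(tx, rec$site_end + 1L, min(L, rec$site_end + fw))
    ext <- substr(tx, max(0L, rec$site_start - fw) + 1L,
                  min(L, rec$site_end + fw))
  } else {
    up <- ""; down <- ""; ext <- site
  }

  out <- numeric(0)
  if ("kmer" %in% config$categories) {
    mk <- kmer_frequencies(mirna, config$kmax)
    sk <- kmer_frequencies(site, config$kmax)
    out <- c(out, stats::setNames(mk, paste0("mir_", names(mk))),
             stats::setNames(sk, paste0("site_", names(sk))))
  }
  if ("pairing" %in% config$categories) {
    pc <- seed_pairing_counts(mirna, site)
    out <- c(out, seed_pairs = pc$seed_pairs, total_pairs = pc$total_pairs,
             pairs_13_16 = pc$pairs_13_16)
  }
  if ("alignment" %in% config$categories) {
    out <- c(out, alignment_score =
               local_alignment_score(mirna, site, config$scoring)$score)
  }
  if ("au" %in% config$categories) {
    out <- c(out, au_flank_up = au_content(up), au_flank_down = au_content(down))
  }
  if ("positional" %in% config$categories) {
    if (has_coord) {
      pf <- positional_features(rec$site_start, rec$site_end, L)
    } else {
      pf <- tibble::tibble(relative_position = 0, distance_from_center = 0,
                           site_length = nchar(site))
    }
    out <- c(out, relative_position = pf$relative_position,
             distance_from_center = pf$distance_from_center,
             site_length = pf$site_length)
  }
  if ("structure" %in% config$categories) {
    sf <- structure_features(ext, engine = config$structure_engine,
                             min_loop = config$min_loop)
    out <- c(out, mfe_proxy = sf$mfe_proxy, open_degree = sf$open_degree,
             paired_fraction = sf$paired_fraction)
  }
  if ("length" %in% config$categories) {
    out <- c(out, mirna_length = nchar(mirna))
  }
  if (!identical(names(out), registry)) {
    bad <- which(names(out) != registry)
    stop(sprintf("feature vector does not match registry at '%s' (expected '%s')",
                 names(out)[bad[1L]], registry[bad[1L]]), call. = FALSE)
  }
  if (any(!is.finite(out))) {
    stop("non-finite feature value for interaction ", rec$mirna_id, "/",
         rec$transcript_id, call. = FALSE)
  }
  out
}

FEATURE_META_COLS <- c("interaction_id", "mirna_id", "transcript_id",
                       "label", "tier")

#' Split a feature tibble into metadata and a numeric matrix
#'
#' @param features A tibble from [build_feature_matrix()].
#' @return A list with `meta` (tibble) and `x` (numeric matrix, one row per
#'   interaction, registry-ordered columns).
#' @export
feature_parts <- function(features) {
  meta_cols <- intersect(FEATURE_META_COLS, names(features))
  fn <- attr(features, "feature_names") %||% setdiff(names(features), meta_cols)
  fn <- intersect(fn, names(features))
  x <- as.matrix(features[fn])
  rownames(x) <- features$interaction_id
  list(meta = features[meta_cols], x = x, feature_names = fn)
}

#' Restrict a feature tibble to a subset of feature columns
#'
#' Keeps the metadata columns, drops all feature columns not in `keep`,
#' and updates the attached feature-name registry (the configuration
#' fingerprint is suffixed with a digest of the selection so that models
#' trained on a subset refuse mismatched screening input).
#'
#' @param features A feature tibble.
#' @param keep Feature names to retain (order taken from the registry).
#' @return The subset tibble with consistent attributes.
#' @export
select_feature_columns <- function(features, keep) {
  parts <- feature_parts(features)
  fn <- parts$feature_names[parts$feature_names %in% keep]
  missing <- setdiff(keep, parts$feature_names)
  if (length(missing) > 0L) {
    stop("unknown feature(s): ", paste(utils::head(missing, 3L), collapse = ", "),
         call. = FALSE)
  }
  out <- dplyr::bind_cols(parts$meta, features[fn])
  attr(out, "feature_names") <- fn
  base_fp <- sub("\\|sel:.*$", "", attr(features, "fingerprint") %||% "unknown")
  attr(out, "fingerprint") <- paste0(base_fp, "|sel:", length(fn), ":",
                                     sum(utf8ToInt(paste(fn, collapse = ""))))
  std <- attr(features, "standardization")
  if (!is.null(std)) {
    attr(out, "standardization") <- list(mean = std$mean[fn], sd = std$sd[fn],
                                         zero_variance = std$zero_variance[fn])
  }
  out
}

#' Standardize feature columns to z-scores
#'
#' Columns are centred to sample mean 0 and scaled to sample standard
#' deviation 1.  Zero-variance columns are set to all-zero and flagged
#' rather than dropped, so vector length is stable across folds and
#' screening.  The standardization parameters are stored in the
#' `"standardization"` attribute so screening-time vectors can be
#' transformed with training-time parameters via [apply_standardization()].
#'
#' @param features Feature tibble from [build_feature_matrix()] (n >= 2).
#' @return The standardized tibble, with attribute `"standardization"`
#'   (a list with `mean`, `sd`, `zero_variance`).
#' @export
standardize_features <- function(features) {
  parts <- feature_parts(features)
  if (nrow(parts$x) < 2L) stop("standardization needs n >= 2", call. = FALSE)
  mu <- colMeans(parts$x)
  sdv <- apply(parts$x, 2L, stats::sd)
  zero <- sdv < .Machine$double.eps^0.5
  params <- list(mean = mu, sd = sdv, zero_variance = zero)
  out <- apply_standardization(features, params)
  out
}

#' Apply stored standardization parameters to a feature tibble
#'
#' @param features Feature tibble with the same registry columns.
#' @param params A standardization parameter list (`mean`, `sd`,
#'   `zero_variance`) as stored by [standardize_features()].
#' @return The transformed tibble, with the parameters attached.
#' @export
apply_standardization <- function(features, params) {
  parts <- feature_parts(features)
  fn <- parts$feature_names
  if (!all(fn %in% names(params$mean))) {
    stop("standardization parameters do not cover all feature columns",
         call. = FALSE)
  }
  x <- sweep(parts$x, 2L, params$mean[fn], "-")
  sdv <- params$sd[fn]
  zero <- params$zero_variance[fn]
  sdv[zero] <- 1
  x <- sweep(x, 2L, sdv, "/")
  x[, zero] <- 0
  out <- dplyr::bind_cols(parts$meta, tibble::as_tibble(x))
  attr(out, "feature_names") <- fn
  attr(out, "fingerprint") <- attr(features, "fingerprint")
  attr(out, "standardization") <- params
  out
}
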