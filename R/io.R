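#' Read miRNA or transcript sequences from a FASTA file
#'
#' Sequences are normalized to the RNA alphabet: lower case is folded to
#' upper case and `T` is mapped to `U` (CLIP/CLASH-derived tables mix DNA and
#' RNA conventions).  Any residue outside `A/C/G/U/T` is a parse error that
#' names the offending line; duplicated identifiers are an error.
#'
#' @param path Path to a FASTA file.
#' @param kind Either `"miRNA"` or `"transcript"`; recorded on every row.
#' @return A tibble with columns `id`, `kind`, `residues`, `length`, one row
#'   per FASTA entry, in file order.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">mir-1", "UGGAAUGUAAAGAAGUAUGUAT"), fa)
#' read_fasta(fa, kind = "miRNA")
#' @export
read_fasta <- function(path, kind = c("miRNA", "transcript")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*$", lines) | seq_along(lines) < length(lines)]
  if (length(lines) == 0L) stop("empty FASTA file: ", path, call. = FALSE)

  header_at <- grepl("^>", lines)
  if (!header_at[1L]) {
    stop(sprintf("%s:1: expected FASTA header line starting with '>'", path),
         call. = FALSE)
  }
  ids <- character(0)
  seqs <- character(0)
  current <- character(0)
  current_id <- NULL
  for (ln in seq_along(lines)) {
    line <- lines[ln]
    if (grepl("^>", line)) {
      if (!is.null(current_id)) {
        if (length(current) == 0L) {
          stop(sprintf("%s: record '%s' has no sequence", path, current_id),
               call. = FALSE)
        }
        ids <- c(ids, current_id)
        seqs <- c(seqs, paste(current, collapse = ""))
      }
      current_id <- sub("^>\\s*", "", line)
      current_id <- sub("\\s.*$", "", current_id)
      if (nchar(current_id) == 0L) {
        stop(sprintf("%s:%d: malformed FASTA header", path, ln), call. = FALSE)
      }
      current <- character(0)
    } else {
      body <- gsub("\\s", "", line)
      up <- gsub("T", "U", toupper(body), fixed = TRUE)
      bad <- regexpr("[^ACGU]", up)
      if (bad > 0L) {
        stop(sprintf("%s:%d: illegal residue '%s' at column %d", path, ln,
                     substr(body, bad, bad), bad), call. = FALSE)
      }
      current <- c(current, up)
    }
  }
  if (is.null(current_id) || length(current) == 0L) {
    stop(sprintf("%s: record '%s' has no sequence", path,
                 current_id %||% "<none>"), call. = FALSE)
  }
  ids <- c(ids, current_id)
  seqs <- c(seqs, paste(current, collapse = ""))

  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L) {
    stop(sprintf("%s: duplicated sequence id(s): %s", path,
                 paste(unique(dup), collapse = ", ")), call. = FALSE)
  }
  tibble::tibble(id = ids, kind = kind, residues = seqs,
                 length = nchar(seqs))
}

#' Write sequences to a FASTA file
#'
#' @param sequences A tibble with columns `id` and `residues`
#'   (as returned by [read_fasta()]).
#' @param path Output path.
#' @param width Line width for the sequence body.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path, width = 70L) {
  stopifnot(all(c("id", "residues") %in% names(sequences)))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(sequences))) {
    writeLines(paste0(">", sequences$id[i]), con)
    s <- sequences$residues[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

INTERACTION_COLUMNS <- c("mirna_id", "transcript_id", "site_start", "site_end",
                         "site_seq", "label", "tier", "source")

#' Read an interaction table
#'
#' Interactions are tab-separated with a header row naming the columns
#' `mirna_id`, `transcript_id`, `site_start`, `site_end`, `site_seq`,
#' `label`, `tier`, `source`.  Coordinates are 0-based, half-open, on the
#' transcript sense strand.  Each record is validated: the site sequence
#' length must equal `site_end - site_start` when coordinates are present,
#' sites must span at least a seed region (8 nt), `label` must be one of
#' `positive`/`negative`/`unknown`, and `tier` (1-4) may only be set on
#' synthesized negatives.
#'
#' @param path Path to a tab-separated interaction table.
#' @return A tibble of validated interactions.
#' @export
read_interactions <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- readr::read_tsv(
    path, show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(
      mirna_id = readr::col_character(),
      transcript_id = readr::col_character(),
      site_start = readr::col_integer(),
      site_end = readr::col_integer(),
      site_seq = readr::col_character(),
      label = readr::col_character(),
      tier = readr::col_integer(),
      source = readr::col_character()
    )
  )
  missing <- setdiff(setdiff(INTERACTION_COLUMNS, c("tier", "source")), names(tab))
  if (length(missing) > 0L) {
    stop("interaction table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!"tier" %in% names(tab)) tab$tier <- NA_integer_
  if (!"source" %in% names(tab)) tab$source <- NA_character_
  validate_interactions(tab[INTERACTION_COLUMNS])
}

#' Validate an in-memory interaction table
#'
#' @param interactions A data frame with the interaction-table columns.
#' @return The validated tibble (site sequences normalized to RNA).
#' @export
validate_interactions <- function(interactions) {
  tab <- tibble::as_tibble(interactions)
  tab$site_seq <- normalize_rna(tab$site_seq, context = "site_seq")
  rec <- function(i) paste0(tab$mirna_id[i], "/", tab$transcript_id[i])

  bad_label <- which(!tab$label %in% c("positive", "negative", "unknown"))
  if (length(bad_label) > 0L) {
    stop(sprintf("record %s: unknown label '%s'", rec(bad_label[1L]),
                 tab$label[bad_label[1L]]), call. = FALSE)
  }
  has_coord <- !is.na(tab$site_start) & !is.na(tab$site_end)
  mismatch <- which(has_coord &
                      (tab$site_end - tab$site_start) != nchar(tab$site_seq))
  if (length(mismatch) > 0L) {
    stop(sprintf(
      "record %s: site_end - site_start = %d but site_seq has %d nt",
      rec(mismatch[1L]),
      tab$site_end[mismatch[1L]] - tab$site_start[mismatch[1L]],
      nchar(tab$site_seq[mismatch[1L]])), call. = FALSE)
  }
  neg_start <- which(has_coord & (tab$site_start < 0L | tab$site_end <= tab$site_start))
  if (length(neg_start) > 0L) {
    stop(sprintf("record %s: invalid coordinates [%d, %d)", rec(neg_start[1L]),
                 tab$site_start[neg_start[1L]], tab$site_end[neg_start[1L]]),
         call. = FALSE)
  }
  short <- which(nchar(tab$site_seq) < 8L)
  if (length(short) > 0L) {
    stop(sprintf("record %s: site shorter than a seed region (%d nt < 8 nt)",
                 rec(short[1L]), nchar(tab$site_seq[short[1L]])), call. = FALSE)
  }
  bad_tier <- which(!is.na(tab$tier) &
                      (tab$label != "negative" | !tab$tier %in% 1:4))
  if (length(bad_tier) > 0L) {
    stop(sprintf("record %s: tier may only be 1-4 on synthesized negatives",
                 rec(bad_tier[1L])), call. = FALSE)
  }
  tab
}

#' Write an interaction table
#'
#' @param interactions A tibble of interactions.
#' @param path Output path (tab-separated, with header).
#' @return `path`, invisibly.
#' @export
write_interactions <- function(interactions, path) {
  tab <- validate_interactions(interactions)
  readr::write_tsv(tab, path, progress = FALSE)
  invisible(path)
}

MODEL_SCHEMA_VERSION <- "1.0"

#' Save a fitted model to JSON
#'
#' Both [dpgmm_fit()] models and [build_cascade()] trees are stored as a
#' single JSON document with an explicit schema-version field, so model
#' files are human-inspectable and diffable.  Numeric fields are written at
#' full precision (17 significant digits), which round-trips IEEE doubles
#' exactly.
#'
#' @param model A `dpgmm_model` or `cascade_dpgmm` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  if (inherits(model, "dpgmm_model")) {
    doc <- list(schema_version = MODEL_SCHEMA_VERSION, type = "dpgmm_model",
                model = serialize_dpgmm(model))
  } else if (inherits(model, "cascade_dpgmm")) {
    doc <- list(schema_version = MODEL_SCHEMA_VERSION, type = "cascade_dpgmm",
                model = serialize_cascade(model))
  } else {
    stop("`model` must be a dpgmm_model or cascade_dpgmm object", call. = FALSE)
  }
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = I(17),
                           null = "null", na = "null")
  writeLines(json, path)
  invisible(path)
}

#' Load a model saved with [save_model()]
#'
#' @param path Path to a model JSON file.
#' @return The restored `dpgmm_model` or `cascade_dpgmm` object.
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  doc <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                       simplifyMatrix = FALSE),
    error = function(e) stop("cannot parse model file (truncated or not JSON): ",
                             conditionMessage(e), call. = FALSE))
  if (is.null(doc$schema_version) || !identical(doc$schema_version, MODEL_SCHEMA_VERSION)) {
    stop(sprintf("unsupported model schema version '%s' (expected '%s')",
                 doc$schema_version %||% "<missing>", MODEL_SCHEMA_VERSION),
         call. = FALSE)
  }
  switch(doc$type,
    dpgmm_model = deserialize_dpgmm(doc$model),
    cascade_dpgmm = deserialize_cascade(doc$model),
    stop(sprintf("unknown model type '%s'", doc$type %||% "<missing>"),
         call. = FALSE))
}

# --- internal (de)serialization -------------------------------------------

serialize_dpgmm <- function(m) {
  list(
    alpha = m$alpha, sigma2 = m$sigma2, n = m$n, m = m$m,
    feature_names = as.list(m$feature_names),
    seed = m$seed, n_iterations = m$n_iterations,
    sweeps_run = m$sweeps_run, converged = m$converged,
    next_cluster_id = m$next_cluster_id,
    cluster_ids = as.list(m$cluster_ids),
    counts = as.list(m$counts),
    sums = apply(m$sums, 1L, as.list, simplify = FALSE),
    assignments = as.list(m$assignments),
    cluster_labels = if (is.null(m$cluster_labels)) NULL else as.list(m$cluster_labels),
    n_pos = if (is.null(m$n_pos)) NULL else as.list(m$n_pos),
    n_neg = if (is.null(m$n_neg)) NULL else as.list(m$n_neg),
    dominant_mirna = if (is.null(m$dominant_mirna)) NULL else as.list(m$dominant_mirna),
    c_k = if (is.null(m$c_k)) NULL else as.list(m$c_k)
  )
}

deserialize_dpgmm <- function(s) {
  K <- length(s$cluster_ids)
  mdim <- s$m
  sums <- matrix(0, nrow = K, ncol = mdim)
  for (j in seq_len(K)) sums[j, ] <- as.numeric(unlist(s$sums[[j]]))
  colnames(sums) <- as.character(unlist(s$feature_names))
  m <- list(
    alpha = s$alpha, sigma2 = s$sigma2, n = as.integer(s$n), m = as.integer(mdim),
    feature_names = as.character(unlist(s$feature_names)),
    seed = s$seed, n_iterations = as.integer(s$n_iterations),
    sweeps_run = as.integer(s$sweeps_run), converged = isTRUE(s$converged),
    next_cluster_id = as.integer(s$next_cluster_id),
    cluster_ids = as.integer(unlist(s$cluster_ids)),
    counts = as.integer(unlist(s$counts)),
    sums = sums,
    assignments = as.integer(unlist(s$assignments))
  )
  if (!is.null(s$cluster_labels)) m$cluster_labels <- as.character(unlist(s$cluster_labels))
  if (!is.null(s$n_pos)) m$n_pos <- as.integer(unlist(s$n_pos))
  if (!is.null(s$n_neg)) m$n_neg <- as.integer(unlist(s$n_neg))
  if (!is.null(s$dominant_mirna)) m$dominant_mirna <- as.character(unlist(s$dominant_mirna))
  if (!is.null(s$c_k)) m$c_k <- as.numeric(unlist(s$c_k))
  m$means <- dpgmm_posterior_means(m$sums, m$counts, m$sigma2)
  class(m) <- "dpgmm_model"
  m
}

serialize_cascade_node <- function(node) {
  list(
    node_id = node$node_id, depth = node$depth, status = node$status,
    n = node$n, label = node$label,
    dominant_mirna = node$dominant_mirna, c_k = node$c_k,
    mirna_homogeneity = node$mirna_homogeneity,
    mrna_homogeneity = node$mrna_homogeneity,
    members = as.list(node$members),
    center = if (is.null(node$center)) NULL else as.list(node$center),
    model = if (is.null(node$model)) NULL else serialize_dpgmm(node$model),
    children = if (length(node$children) == 0L) NULL else
      lapply(node$children, serialize_cascade_node),
    child_cluster_ids = if (length(node$children) == 0L) NULL else
      as.list(as.integer(names(node$children)))
  )
}

deserialize_cascade_node <- function(s) {
  node <- list(
    node_id = s$node_id, depth = as.integer(s$depth), status = s$status,
    n = as.integer(s$n), label = s$label,
    dominant_mirna = if (is.null(s$dominant_mirna)) NA_character_ else s$dominant_mirna,
    c_k = if (is.null(s$c_k)) NA_real_ else as.numeric(s$c_k),
    mirna_homogeneity = if (is.null(s$mirna_homogeneity)) NA_real_ else as.numeric(s$mirna_homogeneity),
    mrna_homogeneity = if (is.null(s$mrna_homogeneity)) NA_real_ else as.numeric(s$mrna_homogeneity),
    members = as.integer(unlist(s$members)),
    center = if (is.null(s$center)) NULL else as.numeric(unlist(s$center)),
    model = if (is.null(s$model)) NULL else deserialize_dpgmm(s$model),
    children = list()
  )
  if (!is.null(s$children)) {
    kids <- lapply(s$children, deserialize_cascade_node)
    names(kids) <- as.character(unlist(s$child_cluster_ids))
    node$children <- kids
  }
  node
}

serialize_cascade <- function(tree) {
  list(
    config = tree$config,
    feature_names = as.list(tree$feature_names),
    fingerprint = tree$fingerprint,
    standardization = list(mean = as.list(tree$standardization$mean),
                           sd = as.list(tree$standardization$sd)),
    seed = tree$seed,
    root = serialize_cascade_node(tree$root)
  )
}

deserialize_cascade <- function(s) {
  fn <- as.character(unlist(s$feature_names))
  std_mean <- as.numeric(unlist(s$standardization$mean))
  std_sd <- as.numeric(unlist(s$standardization$sd))
  names(std_mean) <- fn
  names(std_sd) <- fn
  tree <- list(
    config = s$config,
    feature_names = fn,
    fingerprint = s$fingerprint,
    standardization = list(mean = std_mean, sd = std_sd),
    seed = s$seed,
    root = deserialize_cascade_node(s$root)
  )
  class(tree) <- "cascade_dpgmm"
  tree
}
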