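# Complementarity alignment (Smith-Waterman against the reversed site, so
# the duplex is scored antiparallel) and maximum base-pairing secondary
# structure (Nussinov) used as the built-in accessibility engine.

#' Alignment scoring parameters
#'
#' Scoring scheme for the complementarity alignment of a miRNA against a
#' candidate site.  A Watson-Crick pair (A:U, G:C) scores `match`, a G:U
#' wobble scores `wobble`, any other juxtaposition scores `mismatch`, and
#' each gapped position costs `gap` (linear gap penalty).
#'
#' @param match Score for a Watson-Crick pair.
#' @param wobble Score for a G:U wobble pair.
#' @param mismatch Score for a non-pairing juxtaposition.
#' @param gap Linear per-position gap penalty (applied as `-gap`).
#' @return A list of class `align_params`.
#' @export
align_params <- function(match = 2, wobble = 1, mismatch = -1, gap = 2) {
  stopifnot(is.numeric(match), is.numeric(wobble), is.numeric(mismatch),
            is.numeric(gap), gap >= 0)
  structure(list(match = match, wobble = wobble, mismatch = mismatch,
                 gap = gap), class = "align_params")
}

# Base codes: A C G U = 1..4, masked/other = 5.
encode_rna <- function(chars) {
  code <- match(chars, c("A", "C", "G", "U"))
  code[is.na(code)] <- 5L
  code
}

# 5x5 juxtaposition score table under `params`; row = miRNA base, column =
# reversed-site base.  Masked bases never pair (large negative score).
pair_score_table <- function(params) {
  tab <- matrix(params$mismatch, 5L, 5L)
  wc <- rbind(c(1L, 4L), c(4L, 1L), c(2L, 3L), c(3L, 2L))
  tab[wc] <- params$match
  wob <- rbind(c(3L, 4L), c(4L, 3L))
  tab[wob] <- params$wobble
  tab[5L, ] <- -1e9
  tab[, 5L] <- -1e9
  tab
}

# Smith-Waterman on two encoded vectors; filled along antidiagonals so each
# wavefront is a single vectorized update.  Returns the full (n+1)x(m+1)
# score matrix.
sw_matrix <- function(a_code, b_code, params) {
  n <- length(a_code)
  m <- length(b_code)
  S <- pair_score_table(params)[cbind(rep(a_code, times = m),
                                      rep(b_code, each = n))]
  dim(S) <- c(n, m)
  H <- matrix(0, n + 1L, m + 1L)
  gap <- params$gap
  for (d in 2L:(n + m)) {
    i <- max(1L, d - m):min(n, d - 1L)
    j <- d - i
    cell <- cbind(i + 1L, j + 1L)
    diag_ <- H[cbind(i, j)] + S[cbind(i, j)]
    up <- H[cbind(i, j + 1L)] - gap
    left <- H[cbind(i + 1L, j)] - gap
    H[cell] <- pmax(0, diag_, up, left)
  }
  H
}

sw_traceback <- function(H, a_code, b_code, params) {
  S <- pair_score_table(params)
  best <- which(H == max(H), arr.ind = TRUE)
  # deterministic tie-break: smallest row, then column
  best <- best[order(best[, 1L], best[, 2L]), , drop = FALSE][1L, ]
  i <- unname(best[1L]) - 1L
  j <- unname(best[2L]) - 1L
  end_i <- i; end_j <- j
  while (i > 0L && j > 0L && H[i + 1L, j + 1L] > 0) {
    h <- H[i + 1L, j + 1L]
    if (h == H[i, j] + S[a_code[i], b_code[j]]) {
      i <- i - 1L; j <- j - 1L
    } else if (h == H[i, j + 1L] - params$gap) {
      i <- i - 1L
    } else {
      j <- j - 1L
    }
  }
  list(score = H[end_i + 1L, end_j + 1L],
       a_start = i, a_end = end_i,      # 0-based half-open on sequence a
       b_start = j, b_end = end_j)      # 0-based half-open on sequence b
}

#' Local complementarity alignment of a miRNA against a candidate site
#'
#' The miRNA (5'->3') is aligned against the *reversed* site sequence, so
#' that the optimal local alignment corresponds to an antiparallel
#' miRNA:mRNA duplex.  Scores follow [align_params()]; the score is the
#' Smith-Waterman local maximum and is therefore never negative.
#'
#' @param mirna miRNA sequence (RNA or DNA alphabet; normalized).
#' @param site_seq Candidate binding-site sequence.
#' @param scoring An [align_params()] object.
#' @return A one-row tibble with `score`, the aligned miRNA span
#'   (`mirna_start`, `mirna_end`; 0-based half-open) and the aligned span on
#'   the site in its original orientation (`site_start`, `site_end`).
#' @examples
#' local_alignment_score("AAAA", "UUUU")   # four A:U pairs, score 8
#' @export
local_alignment_score <- function(mirna, site_seq, scoring = align_params()) {
  mirna <- normalize_rna(mirna, "mirna")
  site_seq <- normalize_rna(site_seq, "site_seq")
  a <- encode_rna(strsplit(mirna, "")[[1L]])
  b <- encode_rna(rev(strsplit(site_seq, "")[[1L]]))
  H <- sw_matrix(a, b, scoring)
  tb <- sw_traceback(H, a, b, scoring)
  L <- length(b)
  tibble::tibble(
    score = tb$score,
    mirna_start = tb$a_start, mirna_end = tb$a_end,
    site_start = L - tb$b_end, site_end = L - tb$b_start
  )
}

# --- Nussinov maximum base pairing ----------------------------------------

# TRUE where codes a,b can pair (Watson-Crick or G:U wobble).
PAIRABLE <- local({
  p <- matrix(FALSE, 5L, 5L)
  pairs <- rbind(c(1L, 4L), c(4L, 1L), c(2L, 3L), c(3L, 2L),
                 c(3L, 4L), c(4L, 3L))
  p[pairs] <- TRUE
  p
})

# Watson-Crick pairs only.
PAIRABLE_WC <- local({
  p <- matrix(FALSE, 5L, 5L)
  pairs <- rbind(c(1L, 4L), c(4L, 1L), c(2L, 3L), c(3L, 2L))
  p[pairs] <- TRUE
  p
})

#' Maximum base-pairing structure of an RNA sequence
#'
#' Computes the Nussinov maximum-pairing secondary structure with
#' Watson-Crick and G:U pairs and a minimum hairpin loop of `min_loop`
#' unpaired bases (a base at position `i` may only pair with `j` when
#' `j - i > min_loop`).  Used as the built-in accessibility engine: the
#' negated pair count is a free-energy proxy and the unpaired fraction is
#' the open degree of the site.
#'
#' @param seq RNA sequence.
#' @param min_loop Minimum number of unpaired bases enclosed by a pair.
#' @return A list with `max_pairs`, `paired` (logical per position) and
#'   `structure` (dot-bracket string).
#' @export
nussinov_fold <- function(seq, min_loop = 3L) {
  seq <- normalize_rna(seq, "seq")
  x <- encode_rna(strsplit(seq, "")[[1L]])
  n <- length(x)
  min_loop <- as.integer(min_loop)
  M <- matrix(0L, n, n)
  if (n > min_loop + 1L) {
    for (span in (min_loop + 1L):(n - 1L)) {
      for (ii in 1L:(n - span)) {
        jj <- ii + span
        best <- M[ii, jj - 1L]               # jj unpaired
        k <- ii:(jj - min_loop - 1L)
        k <- k[PAIRABLE[cbind(x[k], rep(x[jj], length(k)))]]
        if (length(k) > 0L) {
          # M's lower triangle is zero, so M[ii, k-1] is 0 exactly when the
          # pair (k, jj) leaves nothing to the left of k
          left <- numeric(length(k))
          sel <- k > ii
          left[sel] <- M[cbind(rep(ii, sum(sel)), k[sel] - 1L)]
          inner <- M[cbind(k + 1L, rep(jj - 1L, length(k)))]
          best <- max(best, max(left + inner + 1L))
        }
        M[ii, jj] <- best
      }
    }
  }
  paired_with <- integer(n) # 0 = unpaired
  if (n >= 2L) {
    stack <- list(c(1L, n))
    while (length(stack) > 0L) {
      ij <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      i <- ij[1L]; j <- ij[2L]
      if (i >= j || j - i <= 0L) next
      if (M[i, j] == 0L) next
      if (M[i, j] == M[i, j - 1L]) {
        stack[[length(stack) + 1L]] <- c(i, j - 1L)
        next
      }
      found <- FALSE
      for (k in i:(j - min_loop - 1L)) {
        if (!PAIRABLE[x[k], x[j]]) next
        left <- if (k > i) M[i, k - 1L] else 0L
        inner <- if (k + 1L <= j - 1L) M[k + 1L, j - 1L] else 0L
        if (M[i, j] == left + inner + 1L) {
          paired_with[k] <- j
          paired_with[j] <- k
          if (k > i) stack[[length(stack) + 1L]] <- c(i, k - 1L)
          if (k + 1L <= j - 1L) stack[[length(stack) + 1L]] <- c(k + 1L, j - 1L)
          found <- TRUE
          break
        }
      }
      if (!found) stack[[length(stack) + 1L]] <- c(i, j - 1L)
    }
  }
  paired <- paired_with > 0L
  db <- rep(".", n)
  db[paired & seq_len(n) < paired_with] <- "("
  db[paired & seq_len(n) > paired_with] <- ")"
  list(max_pairs = if (n >= 2L) M[1L, n] else 0L,
       paired = paired,
       structure = paste(db, collapse = ""))
}
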