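# Internal helpers shared across modules.

RNA_BASES <- c("A", "C", "G", "U")

#' @keywords internal
#' @noRd
normalize_rna <- function(x, context = "sequence") {
  x <- toupper(x)
  x <- gsub("T", "U", x, fixed = TRUE)
  bad <- regexpr("[^ACGU]", x)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1L]
    stop(sprintf("illegal residue '%s' at position %d in %s",
                 substr(x[i], bad[i], bad[i]), bad[i], context), call. = FALSE)
  }
  if (any(nchar(x) == 0L)) {
    stop(sprintf("empty %s", context), call. = FALSE)
  }
  x
}

# Watson-Crick complement (RNA).
RNA_COMPLEMENT <- c(A = "U", C = "G", G = "C", U = "A")

#' @keywords internal
#' @noRd
rna_complement <- function(x) {
  chartr("ACGU", "UGCA", x)
}

#' @keywords internal
#' @noRd
rna_reverse <- function(x) {
  vapply(x, function(s) paste(rev(strsplit(s, "")[[1L]]), collapse = ""), "",
         USE.NAMES = FALSE)
}

#' @keywords internal
#' @noRd
rna_revcomp <- function(x) {
  rna_complement(rna_reverse(x))
}

# TRUE where a:b is a Watson-Crick pair.
#' @keywords internal
#' @noRd
is_wc_pair <- function(a, b) {
  (a == "A" & b == "U") | (a == "U" & b == "A") |
    (a == "G" & b == "C") | (a == "C" & b == "G")
}

# TRUE where a:b is a G:U wobble.
#' @keywords internal
#' @noRd
is_wobble_pair <- function(a, b) {
  (a == "G" & b == "U") | (a == "U" & b == "G")
}

#' @keywords internal
#' @noRd
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Deterministic child seed from a parent seed and a stream label; stays
# below 2^31 so it is always a valid R integer seed.
#' @keywords internal
#' @noRd
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(as.character(label)) * seq_along(utf8ToInt(as.character(label))))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

#' @keywords internal
#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
#' @noRd
assert_scalar_number <- function(x, name, lower = -Inf, strict = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (strict) x > lower else x >= lower)
  if (!ok) {
    stop(sprintf("`%s` must be a finite number %s %s", name,
                 if (strict) ">" else ">=", format(lower)), call. = FALSE)
  }
  invisible(x)
}
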