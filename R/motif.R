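# Residue/motif patterns over generic positions. One character per
# expanded position: a literal residue or one of the seven
# physicochemical wildcards. Inside a motif string '-' is the
# negatively-charged wildcard (D/E); inside a sequence it is a gap -- the
# two contexts never mix because motif strings cannot contain gaps.

#' Parse a residue/motif pattern
#'
#' Each character of the pattern is either a one-letter residue code
#' (matching only itself) or a one-character wildcard from
#' [wildcard_classes()]. Input is case-insensitive and canonicalized to
#' uppercase.
#'
#' @param text Pattern string, e.g. `"NP"`, `"@"`, `"~P@"`.
#' @return A `gpcr_motif`: the raw pattern plus one allowed-residue set
#'   per pattern position.
#' @examples
#' parse_motif("~P@")
#' @export
parse_motif <- function(text) {
  if (inherits(text, "gpcr_motif")) {
    return(text)
  }
  stopifnot(is.character(text), length(text) == 1L)
  text <- toupper(trimws(text))
  if (!nzchar(text)) {
    gpcr_error("gpcr_motif_error", "empty motif pattern")
  }
  chars <- strsplit(text, "")[[1L]]
  classes <- lapply(chars, function(ch) {
    if (ch %in% AA_ALPHABET) {
      ch
    } else if (ch %in% names(WILDCARD_CLASSES)) {
      WILDCARD_CLASSES[[ch]]
    } else {
      gpcr_error("gpcr_motif_error", "unknown motif character '%s'", ch)
    }
  })
  structure(list(raw = text, classes = classes), class = "gpcr_motif")
}

#' @export
format.gpcr_motif <- function(x, ...) x$raw

#' @export
print.gpcr_motif <- function(x, ...) {
  cat("<gpcr_motif> ", x$raw, "\n", sep = "")
  for (k in seq_along(x$classes)) {
    cat(sprintf("  [%d] {%s}\n", k, paste(x$classes[[k]], collapse = "")))
  }
  invisible(x)
}

#' Test which sequences match a motif at given columns
#'
#' A sequence matches when, at every queried column, its residue belongs
#' to the corresponding allowed set. A gap at any queried column makes the
#' match undetermined (`NA`): such sequences are excluded from both
#' numerator and denominator of every downstream percentage.
#'
#' @param motif A `gpcr_motif` or pattern string.
#' @param aln A `gpcr_alignment`.
#' @param columns Integer alignment columns, one per pattern position.
#' @return Named logical vector over sequences; `NA` marks gapped
#'   (undetermined) sequences.
#' @export
motif_matches <- function(motif, aln, columns) {
  motif <- parse_motif(motif)
  stopifnot(inherits(aln, "gpcr_alignment"))
  if (length(motif$classes) != length(columns)) {
    gpcr_error("gpcr_arity_error",
               "motif has %d positions but %d columns were given",
               length(motif$classes), length(columns))
  }
  mat <- aln$matrix[, columns, drop = FALSE]
  ok <- matrix(TRUE, nrow = nrow(mat), ncol = ncol(mat))
  gapped <- mat == GAP_CHAR
  for (k in seq_along(columns)) {
    ok[, k] <- mat[, k] %in% motif$classes[[k]]
  }
  res <- rowSums(ok) == length(columns)
  res[rowSums(gapped) > 0L] <- NA
  names(res) <- rownames(aln$matrix)
  res
}
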