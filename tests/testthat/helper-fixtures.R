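# Builders for small in-memory alignments used across the suite.

AAS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
         "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Build an alignment from a list of column residue vectors (all the same
# length); default metadata marks everything human class A non-olfactory.
aln_from_cols <- function(cols, labels = NULL, metadata = NULL) {
  n <- length(cols[[1L]])
  stopifnot(all(vapply(cols, length, integer(1L)) == n))
  seqs <- vapply(seq_len(n), function(r) {
    paste(vapply(cols, `[[`, character(1L), r), collapse = "")
  }, character(1L))
  names(seqs) <- if (is.null(metadata)) {
    sprintf("SEQ%03d_HUMAN", seq_len(n))
  } else {
    metadata$entry_name
  }
  if (is.null(labels)) {
    labels <- paste0("1.", 49L + seq_along(cols))
  }
  gpcr_alignment(seqs, labels, metadata)
}

# Random gap-free alignment matrix over a reduced alphabet (keeps joint
# tables small enough for brute-force oracles).
random_aln <- function(n, L, alphabet = AAS[1:6], gap_rate = 0) {
  cols <- lapply(seq_len(L), function(j) {
    prof <- as.numeric(stats::rmultinom(1L, 50L, rep(1, length(alphabet)))) + 1
    col <- sample(alphabet, n, replace = TRUE, prob = prof)
    if (gap_rate > 0) col[stats::runif(n) < gap_rate] <- "-"
    col
  })
  aln_from_cols(cols)
}

# Metadata helper with scheme paths per sequence.
meta_with_scheme <- function(entry, gpcr_class, taxon, olfactory, paths,
                             scheme = "fredriksson") {
  md <- data.frame(entry_name = entry, gpcr_class = gpcr_class,
                   taxon_group = taxon, olfactory = olfactory,
                   stringsAsFactors = FALSE, check.names = FALSE)
  md[[paste0("scheme:", scheme)]] <- paths
  md
}
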