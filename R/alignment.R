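# The aligned sequence universe: fixed-length aligned sequences over the
# 20-residue alphabet plus '-', a map from alignment columns to generic
# (Ballesteros-Weinstein style) position labels, and per-receptor
# metadata (class, taxon, olfactory flag, hierarchical classification
# paths per scheme).

required_metadata_cols <- c("entry_name", "gpcr_class", "taxon_group", "olfactory")

# Internal constructor + validator. `position_map` must already carry
# column (1-based), label, helix, index.
new_gpcr_alignment <- function(sequences, position_map, metadata) {
  if (length(sequences) == 0L) {
    gpcr_error("gpcr_empty_selection", "alignment contains no sequences")
  }
  if (is.null(names(sequences)) || anyDuplicated(names(sequences))) {
    gpcr_error("gpcr_consistency_error", "sequence entry names must be unique")
  }
  widths <- nchar(sequences)
  if (length(unique(widths)) != 1L) {
    gpcr_error("gpcr_shape_error",
               "ragged alignment: sequence lengths %s",
               paste(sort(unique(widths)), collapse = ", "))
  }
  L <- widths[[1L]]
  mat <- matrix(unlist(strsplit(sequences, ""), use.names = FALSE),
                nrow = length(sequences), ncol = L, byrow = TRUE,
                dimnames = list(names(sequences), NULL))
  bad <- setdiff(unique(as.vector(mat)), c(AA_ALPHABET, GAP_CHAR))
  if (length(bad) > 0L) {
    gpcr_error("gpcr_alphabet_error",
               "unknown residue symbol(s): %s", paste(sQuote(bad), collapse = ", "))
  }

  # position map must label every column exactly once, in increasing order
  stopifnot(is.data.frame(position_map),
            all(c("column", "label") %in% names(position_map)))
  pm <- position_map
  if (nrow(pm) != L || !identical(as.integer(pm$column), seq_len(L))) {
    gpcr_error("gpcr_shape_error",
               "position map must label all %d alignment columns exactly once", L)
  }
  if (anyDuplicated(pm$label)) {
    gpcr_error("gpcr_consistency_error", "duplicated generic position labels")
  }
  parsed <- lapply(pm$label, parse_label)
  pm$helix <- vapply(parsed, `[[`, integer(1L), "helix")
  pm$index <- vapply(parsed, `[[`, integer(1L), "index")
  pm <- pm[, c("column", "label", "helix", "index")]

  stopifnot(is.data.frame(metadata))
  miss <- setdiff(required_metadata_cols, names(metadata))
  if (length(miss) > 0L) {
    gpcr_error("gpcr_consistency_error",
               "metadata lacks column(s): %s", paste(miss, collapse = ", "))
  }
  if (!setequal(metadata$entry_name, names(sequences)) ||
      nrow(metadata) != length(sequences)) {
    gpcr_error("gpcr_consistency_error",
               "metadata entry names do not match the alignment (one record per sequence)")
  }
  metadata <- metadata[match(names(sequences), metadata$entry_name), , drop = FALSE]
  rownames(metadata) <- NULL
  if (!all(metadata$gpcr_class %in% GPCR_CLASSES)) {
    gpcr_error("gpcr_consistency_error", "gpcr_class must be one of A, B, C, F")
  }
  if (!all(metadata$taxon_group %in% TAXON_GROUPS)) {
    gpcr_error("gpcr_consistency_error", "taxon_group must be one of %s",
               paste(TAXON_GROUPS, collapse = ", "))
  }
  metadata$olfactory <- as.logical(metadata$olfactory)
  if (anyNA(metadata$olfactory)) {
    gpcr_error("gpcr_consistency_error", "olfactory flag must be TRUE or FALSE")
  }

  structure(
    list(sequences = sequences, matrix = mat, position_map = pm,
         metadata = metadata, cache = new.env(parent = emptyenv())),
    class = "gpcr_alignment"
  )
}

#' Construct an aligned GPCR sequence set in memory
#'
#' Builds the validated container every analysis runs over: aligned
#' sequences, a column-to-generic-label position map, and per-receptor
#' metadata. Sequences must all have the same length and use only the 20
#' uppercase one-letter residue codes plus `'-'` for gaps (ambiguity codes
#' are rejected).
#'
#' @param sequences Named character vector of aligned sequences; names are
#'   UniProt-style entry names (e.g. `"ADRB2_HUMAN"`).
#' @param labels Character vector of generic position labels (`"h.nn"`,
#'   helix 1-8), one per alignment column, in column order.
#' @param metadata Data frame with columns `entry_name`, `gpcr_class`
#'   (A/B/C/F), `taxon_group` (human/mammal/vertebrate/eukaryote/other),
#'   `olfactory` (logical) and optionally `scheme:<name>` columns holding
#'   slash-joined hierarchical classification paths (e.g. `"alpha/amine"`).
#'   If omitted, every sequence is recorded as a human, non-olfactory
#'   class A receptor.
#' @return A `gpcr_alignment` object.
#' @examples
#' aln <- gpcr_alignment(
#'   c(R1_HUMAN = "NDRI", R2_HUMAN = "NDRV"),
#'   labels = c("1.50", "2.50", "3.50", "3.51")
#' )
#' aln
#' @export
gpcr_alignment <- function(sequences, labels, metadata = NULL) {
  if (is.null(metadata)) {
    metadata <- data.frame(
      entry_name = names(sequences), gpcr_class = "A",
      taxon_group = "human", olfactory = FALSE,
      check.names = FALSE, stringsAsFactors = FALSE
    )
  }
  pm <- data.frame(column = seq_along(labels), label = labels,
                   stringsAsFactors = FALSE)
  new_gpcr_alignment(sequences, pm, metadata)
}

#' @export
print.gpcr_alignment <- function(x, ...) {
  cat(sprintf("<gpcr_alignment> %d sequences x %d columns (helices %s)\n",
              nrow(x$matrix), ncol(x$matrix),
              paste(sort(unique(x$position_map$helix)), collapse = ",")))
  cls <- table(x$metadata$gpcr_class)
  cat("  classes:", paste(sprintf("%s=%d", names(cls), cls), collapse = " "), "\n")
  invisible(x)
}

#' Number of sequences in an alignment set
#' @param aln A `gpcr_alignment`.
#' @return Integer count.
#' @export
n_sequences <- function(aln) {
  nrow(aln$matrix)
}

#' Load an aligned GPCR sequence set from disk
#'
#' Reads the three standard files: an aligned FASTA (gap character `'-'`,
#' uppercase), a position-map TSV (`column<TAB>label`, header required,
#' columns 0-based) and a metadata TSV (`entry_name`, `gpcr_class`,
#' `taxon_group`, `olfactory`, plus `scheme:<name>` columns). The inputs
#' are cross-validated: ragged alignments, non-standard residue symbols
#' and metadata/sequence name mismatches are rejected.
#'
#' @param fasta_path,posmap_path,metadata_path File paths.
#' @return A validated `gpcr_alignment`.
#' @seealso [write_alignment()] for the inverse; the pair round-trips
#'   byte-identically.
#' @export
read_alignment <- function(fasta_path, posmap_path, metadata_path) {
  for (p in c(fasta_path, posmap_path, metadata_path)) {
    if (!file.exists(p)) gpcr_error("gpcr_not_found", "file not found: %s", p)
  }
  aa <- Biostrings::readAAStringSet(fasta_path)
  sequences <- as.character(aa)
  names(sequences) <- names(aa)

  pm <- utils::read.delim(posmap_path, header = TRUE, sep = "\t",
                          colClasses = "character",   # keep "3.40" verbatim
                          stringsAsFactors = FALSE)
  if (!all(c("column", "label") %in% names(pm))) {
    gpcr_error("gpcr_consistency_error",
               "position map needs 'column' and 'label' columns")
  }
  pm$column <- as.integer(pm$column) + 1L   # file is 0-based
  pm$label <- as.character(pm$label)
  pm <- pm[, c("column", "label")]

  md <- utils::read.delim(metadata_path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  md$olfactory <- toupper(md$olfactory) %in% c("TRUE", "T", "1")

  new_gpcr_alignment(sequences, pm, md)
}

#' Write an aligned GPCR sequence set to disk
#'
#' Writes the three standard files read by [read_alignment()]:
#' `<prefix>.fasta`, `<prefix>_positions.tsv` (0-based columns) and
#' `<prefix>_metadata.tsv`. Output is deterministic, so write/read/write
#' round-trips are byte-identical.
#'
#' @param aln A `gpcr_alignment`.
#' @param dir Output directory (created if missing).
#' @param prefix File name prefix.
#' @return Invisibly, a named character vector of the three paths.
#' @export
write_alignment <- function(aln, dir, prefix = "alignment") {
  stopifnot(inherits(aln, "gpcr_alignment"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    fasta = file.path(dir, paste0(prefix, ".fasta")),
    posmap = file.path(dir, paste0(prefix, "_positions.tsv")),
    metadata = file.path(dir, paste0(prefix, "_metadata.tsv"))
  )
  Biostrings::writeXStringSet(Biostrings::AAStringSet(aln$sequences),
                              filepath = paths[["fasta"]])
  pm_out <- data.frame(column = aln$position_map$column - 1L,
                       label = aln$position_map$label)
  utils::write.table(pm_out, paths[["posmap"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  md_out <- aln$metadata
  md_out$olfactory <- ifelse(md_out$olfactory, "TRUE", "FALSE")
  utils::write.table(md_out, paths[["metadata"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}

#' Filter an alignment set by class, taxon, scheme path and olfactory flag
#'
#' Selection mirrors the navigable classification model: an optional
#' receptor class (A/B/C/F), a cumulative taxonomic set (Human is a subset
#' of Mammals, of Vertebrates, of Eukaryotes, of All), and an optional
#' slash-path prefix within one classification scheme. Olfactory receptors
#' are excluded by default so they do not dominate class A statistics.
#'
#' @param aln A `gpcr_alignment`.
#' @param gpcr_class Optional class, one of `"A"`, `"B"`, `"C"`, `"F"`.
#' @param taxon One of `"Human"`, `"Mammals"`, `"Vertebrates"`,
#'   `"Eukaryotes"`, `"All"`. Sets are cumulative supersets in that order.
#' @param scheme Optional classification scheme name; requires a matching
#'   `scheme:<name>` metadata column.
#' @param path Optional slash-joined path prefix within `scheme`
#'   (`"alpha"` matches `"alpha"` and `"alpha/amine"` but not `"alphax"`).
#' @param include_olfactory Keep olfactory receptors? Default `FALSE`.
#' @return The matching `gpcr_alignment` subset. Selecting twice with the
#'   same filter is a no-op; an empty result is an error, since no
#'   statistic is defined over zero sequences.
#' @examples
#' aln <- default_fixture(seed = 1)
#' select_receptors(aln, gpcr_class = "C", taxon = "Human")
#' @export
select_receptors <- function(aln, gpcr_class = NULL,
                             taxon = c("All", "Human", "Mammals",
                                       "Vertebrates", "Eukaryotes"),
                             scheme = NULL, path = NULL,
                             include_olfactory = FALSE) {
  stopifnot(inherits(aln, "gpcr_alignment"))
  taxon <- match.arg(taxon)
  md <- aln$metadata
  keep <- md$taxon_group %in% TAXON_SETS[[taxon]]
  if (!include_olfactory) {
    keep <- keep & !md$olfactory
  }
  if (!is.null(gpcr_class)) {
    stopifnot(gpcr_class %in% GPCR_CLASSES)
    keep <- keep & md$gpcr_class == gpcr_class
  }
  if (!is.null(path)) {
    if (is.null(scheme)) {
      gpcr_error("gpcr_consistency_error", "a path filter requires a scheme")
    }
    col <- paste0("scheme:", scheme)
    if (!col %in% names(md)) {
      gpcr_error("gpcr_not_found", "unknown classification scheme '%s'", scheme)
    }
    p <- md[[col]]
    p[is.na(p)] <- ""
    keep <- keep & (p == path | startsWith(p, paste0(path, "/")))
  }
  if (!any(keep)) {
    gpcr_error("gpcr_empty_selection", "selection matches no sequences")
  }
  new_gpcr_alignment(aln$sequences[keep], aln$position_map[, c("column", "label")],
                     md[keep, , drop = FALSE])
}
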