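# Position-wise conservation: residue/tuple frequency tables, Shannon
# entropy scaled to [0,1] by log base 20^n, percent occurrence of motifs,
# consensus sequences, and same-level / sub-level category comparisons.

#' Residue (tuple) frequency table at a position set
#'
#' Counts residues (for one position) or residue tuples (for several, in
#' specification order) over the sequences that are gap-free at every
#' queried column. Probabilities are counts divided by that gap-free
#' count, so they always sum to one.
#'
#' @param aln A `gpcr_alignment`.
#' @param positions Position specification (string or `gpcr_positions`).
#' @return A `gpcr_freq`: data frame with `tuple`, `count`, `prob`
#'   (ordered by decreasing count, then tuple), with attributes
#'   `labels`, `n_effective` and `n_positions`.
#' @examples
#' aln <- gpcr_alignment(c(A_HUMAN = "I", B_HUMAN = "I", C_HUMAN = "V"),
#'                       labels = "3.40")
#' frequency_table(aln, "3.40")
#' @export
frequency_table <- function(aln, positions) {
  stopifnot(inherits(aln, "gpcr_alignment"))
  res <- resolve_positions(aln$position_map, positions)
  sub <- aln$matrix[, res$column, drop = FALSE]
  gap_free <- rowSums(sub == GAP_CHAR) == 0L
  if (!any(gap_free)) {
    gpcr_error("gpcr_empty_denominator",
               "all sequences are gapped at position(s) %s",
               paste(res$label, collapse = ","))
  }
  tuples <- apply(sub[gap_free, , drop = FALSE], 1L, paste, collapse = "")
  tab <- table(tuples)
  out <- data.frame(tuple = names(tab), count = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$tuple), , drop = FALSE]
  rownames(out) <- NULL
  out$prob <- out$count / sum(out$count)
  structure(out, labels = res$label, n_effective = sum(gap_free),
            n_positions = nrow(res), class = c("gpcr_freq", "data.frame"))
}

#' Shannon entropy of a position or position tuple, scaled to [0, 1]
#'
#' Computes `H = -sum_x p_x log_b p_x` with `b = 20^n`, `n` the number of
#' queried positions, over the gap-free residue (tuple) distribution. The
#' base makes H range from 0 (a single observed tuple, full conservation)
#' to 1 (uniform over the whole 20^n alphabet, maximal variability).
#' Zero-probability terms contribute zero. A residue tuple is treated as
#' one joint symbol; no independence between positions is assumed.
#'
#' @param x A `gpcr_freq` table, or a `gpcr_alignment` (then `positions`
#'   is required).
#' @param positions Position specification when `x` is an alignment.
#' @return A `gpcr_entropy`: list with `H`, the base `b = 20^n`, and
#'   `n_positions`.
#' @examples
#' aln <- gpcr_alignment(c(A_HUMAN = "I", B_HUMAN = "V"), labels = "3.40")
#' shannon_entropy(aln, "3.40")$H   # ln 2 / ln 20
#' @export
shannon_entropy <- function(x, positions = NULL) {
  ft <- if (inherits(x, "gpcr_alignment")) {
    stopifnot(!is.null(positions))
    frequency_table(x, positions)
  } else {
    stopifnot(inherits(x, "gpcr_freq"))
    x
  }
  n <- attr(ft, "n_positions")
  p <- ft$prob[ft$prob > 0]
  H <- -sum(p * log(p)) / (n * log(20))
  structure(list(H = H, b = 20^n, n_positions = n), class = "gpcr_entropy")
}

#' @export
print.gpcr_entropy <- function(x, ...) {
  cat(sprintf("Shannon entropy H = %.4f (base 20^%d)\n", x$H, x$n_positions))
  invisible(x)
}

#' Percent occurrence of a residue or motif at a position set
#'
#' The percentage of sequences matching the motif among sequences gap-free
#' at every queried column, together with the entry names of the matching
#' receptors.
#'
#' @param aln A `gpcr_alignment`.
#' @param positions Position specification; its expansion must have as
#'   many columns as the motif has pattern positions.
#' @param motif A `gpcr_motif` or pattern string.
#' @return A `gpcr_occurrence`: list with `percent` (full precision;
#'   printed to 1 decimal), `n_match`, `n_effective` and `receptors`.
#' @examples
#' aln <- default_fixture(seed = 1)
#' human_a <- select_receptors(aln, gpcr_class = "A", taxon = "Human")
#' percent_occurrence(human_a, "3.40", "~")
#' @export
percent_occurrence <- function(aln, positions, motif) {
  cols <- columns_for(aln, positions)
  m <- motif_matches(motif, aln, cols)
  n_eff <- sum(!is.na(m))
  if (n_eff == 0L) {
    gpcr_error("gpcr_empty_denominator",
               "no sequence is gap-free at the queried position(s)")
  }
  hits <- names(m)[which(m)]
  structure(
    list(percent = 100 * length(hits) / n_eff, n_match = length(hits),
         n_effective = n_eff, receptors = hits,
         positions = format(parse_positions(positions)),
         motif = parse_motif(motif)$raw),
    class = "gpcr_occurrence"
  )
}

#' @export
print.gpcr_occurrence <- function(x, ...) {
  cat(sprintf("%s at %s: %.1f%% (%d/%d gap-free sequences)\n",
              x$motif, x$positions, x$percent, x$n_match, x$n_effective))
  invisible(x)
}

# Enumerate same-level (sibling) and sub-level (child) categories for a
# classification node given by gpcr_class and/or scheme+path. Each entry
# carries the arguments to select_receptors() that realize the category.
level_categories <- function(aln, gpcr_class = NULL, taxon = "All",
                             scheme = NULL, path = NULL,
                             include_olfactory = FALSE) {
  md <- aln$metadata
  base_keep <- md$taxon_group %in% TAXON_SETS[[taxon]]
  if (!include_olfactory) base_keep <- base_keep & !md$olfactory
  cats <- list()
  scheme_col <- if (!is.null(scheme)) paste0("scheme:", scheme) else NULL
  if (!is.null(scheme_col) && !scheme_col %in% names(md)) {
    gpcr_error("gpcr_not_found", "unknown classification scheme '%s'", scheme)
  }

  paths_under <- function(keep, prefix) {
    p <- md[[scheme_col]][keep]
    p <- p[!is.na(p) & nzchar(p)]
    if (!is.null(prefix)) {
      p <- p[p == prefix | startsWith(p, paste0(prefix, "/"))]
    }
    p
  }
  component <- function(paths, depth) {
    parts <- strsplit(paths, "/", fixed = TRUE)
    out <- vapply(parts, function(x) if (length(x) >= depth) x[depth] else NA_character_,
                  character(1L))
    sort(unique(out[!is.na(out)]))
  }

  # same level: siblings of the scheme node, or the other classes
  if (!is.null(scheme) && !is.null(path)) {
    comps <- strsplit(path, "/", fixed = TRUE)[[1L]]
    depth <- length(comps)
    parent <- if (depth > 1L) paste(comps[-depth], collapse = "/") else NULL
    keep <- base_keep
    if (!is.null(gpcr_class)) keep <- keep & md$gpcr_class == gpcr_class
    sibs <- setdiff(component(paths_under(keep, parent), depth), comps[depth])
    for (s in sibs) {
      spath <- if (is.null(parent)) s else paste(parent, s, sep = "/")
      cats[[length(cats) + 1L]] <- list(
        level = "same", category = spath,
        args = list(gpcr_class = gpcr_class, taxon = taxon, scheme = scheme,
                    path = spath, include_olfactory = include_olfactory))
    }
  } else if (!is.null(gpcr_class)) {
    for (cl in setdiff(sort(unique(md$gpcr_class[base_keep])), gpcr_class)) {
      cats[[length(cats) + 1L]] <- list(
        level = "same", category = paste("class", cl),
        args = list(gpcr_class = cl, taxon = taxon, scheme = NULL,
                    path = NULL, include_olfactory = include_olfactory))
    }
  }

  # sub level: children of the current node within the scheme
  if (!is.null(scheme)) {
    keep <- base_keep
    if (!is.null(gpcr_class)) keep <- keep & md$gpcr_class == gpcr_class
    depth <- if (is.null(path)) 0L else length(strsplit(path, "/", fixed = TRUE)[[1L]])
    kids <- component(paths_under(keep, path), depth + 1L)
    for (k in kids) {
      kpath <- if (is.null(path)) k else paste(path, k, sep = "/")
      cats[[length(cats) + 1L]] <- list(
        level = "sub", category = kpath,
        args = list(gpcr_class = gpcr_class, taxon = taxon, scheme = scheme,
                    path = kpath, include_olfactory = include_olfactory))
    }
  }
  cats
}

#' Compare motif occurrence across sibling and child categories
#'
#' Runs [percent_occurrence()] independently in every category at the same
#' classification level (siblings: the other scheme branches at the node's
#' depth, or the other receptor classes when no scheme path is given) and
#' one level below (children of the node). A node with no siblings yields
#' an empty same-level set; a leaf yields an empty sub-level set.
#' Categories where the percentage is undefined (e.g. all sequences gapped)
#' are reported with `NA`, not dropped.
#'
#' @inheritParams percent_occurrence
#' @param gpcr_class,taxon,scheme,path,include_olfactory Selection naming
#'   the classification node, as in [select_receptors()].
#' @return A `gpcr_levels` data frame: `level` (`"same"`/`"sub"`),
#'   `category`, `percent`, `n_match`, `n_effective`.
#' @export
compare_levels <- function(aln, positions, motif, gpcr_class = NULL,
                           taxon = "All", scheme = NULL, path = NULL,
                           include_olfactory = FALSE) {
  cats <- level_categories(aln, gpcr_class = gpcr_class, taxon = taxon,
                           scheme = scheme, path = path,
                           include_olfactory = include_olfactory)
  rows <- lapply(cats, function(ct) {
    occ <- tryCatch(
      percent_occurrence(do.call(select_receptors, c(list(aln), ct$args)),
                         positions, motif),
      gpcralign_error = function(e) NULL
    )
    data.frame(
      level = ct$level, category = ct$category,
      percent = if (is.null(occ)) NA_real_ else occ$percent,
      n_match = if (is.null(occ)) NA_integer_ else occ$n_match,
      n_effective = if (is.null(occ)) NA_integer_ else occ$n_effective,
      stringsAsFactors = FALSE
    )
  })
  out <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame(level = character(), category = character(),
               percent = numeric(), n_match = integer(),
               n_effective = integer(), stringsAsFactors = FALSE)
  structure(out, class = c("gpcr_levels", "data.frame"))
}

#' Consensus sequence of a selection
#'
#' Per alignment column, the most frequent gap-free residue. Ties are
#' broken lexicographically by one-letter code and flagged; an all-gap
#' column gets consensus `'-'` with frequency 0.
#'
#' @param aln A `gpcr_alignment`.
#' @return Data frame with `column`, `label`, `residue`, `freq`
#'   (modal count over gap-free count) and `tie`.
#' @export
consensus_sequence <- function(aln) {
  stopifnot(inherits(aln, "gpcr_alignment"))
  rows <- lapply(seq_len(ncol(aln$matrix)), function(j) {
    col <- aln$matrix[, j]
    col <- col[col != GAP_CHAR]
    if (length(col) == 0L) {
      return(data.frame(column = j, residue = GAP_CHAR, freq = 0,
                        tie = FALSE, stringsAsFactors = FALSE))
    }
    tab <- table(col)
    top <- names(tab)[tab == max(tab)]
    data.frame(column = j, residue = sort(top)[1L],
               freq = max(tab) / length(col), tie = length(top) > 1L,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$label <- aln$position_map$label[out$column]
  out[, c("column", "label", "residue", "freq", "tie")]
}
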