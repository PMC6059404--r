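# Snake-plot rendering: one circle per mapped generic position, helices
# TM1..TM7 drawn as vertical zigzag columns (odd helices top-down, even
# bottom-up, as the chain snakes through the membrane), helix 8 as a
# horizontal intracellular row. Two conservation channels: the letter in
# a gray gradient (frequency of the displayed residue in the reference
# class set) and the circle outline in a blue gradient (frequency in the
# selected group). In single-receptor mode, residues differing from the
# selection consensus are filled green.
#
# The geometry is a fixed convention (the science is in the shading), so
# renders are byte-stable for a given input.

SNAKE_R <- 9          # glyph radius, px
SNAKE_DX <- 52        # horizontal spacing between helices
SNAKE_DY <- 20        # vertical spacing within a helix
SNAKE_ZIG <- 11       # zigzag offset
SNAKE_MARGIN <- 40
SNAKE_BINS <- 8L      # discrete gradient bins

# frequency in [0,1] -> bin 0..7 -> shade; higher frequency is darker.
shade_bin <- function(freq) {
  pmin(SNAKE_BINS - 1L, floor(pmin(pmax(freq, 0), 1) * SNAKE_BINS))
}

gray_shade <- function(freq) {
  v <- round(205 * (1 - shade_bin(freq) / (SNAKE_BINS - 1L)))
  sprintf("#%02X%02X%02X", v, v, v)
}

blue_shade <- function(freq) {
  v <- round(205 * (1 - shade_bin(freq) / (SNAKE_BINS - 1L)))
  sprintf("#%02X%02XFF", v, v)
}

# Deterministic glyph coordinates for every row of a position map.
snake_layout <- function(posmap) {
  pm <- posmap[order(posmap$column), , drop = FALSE]
  tm <- pm[pm$helix <= 7L, , drop = FALSE]
  h8 <- pm[pm$helix == 8L, , drop = FALSE]
  max_len <- if (nrow(tm) > 0L) max(table(tm$helix)) else 0L
  coords <- lapply(seq_len(nrow(pm)), function(r) NULL)
  for (h in unique(tm$helix)) {
    rows <- which(pm$helix == h)
    k <- length(rows)
    x0 <- SNAKE_MARGIN + (h - 1L) * SNAKE_DX
    for (i in seq_len(k)) {
      slot <- if (h %% 2L == 1L) i - 1L else (k - i)  # odd: down, even: up
      coords[[rows[i]]] <- c(
        x = x0 + (i %% 2L) * SNAKE_ZIG,
        y = SNAKE_MARGIN + slot * SNAKE_DY
      )
    }
  }
  if (nrow(h8) > 0L) {
    y8 <- SNAKE_MARGIN + max_len * SNAKE_DY + 30
    rows <- which(pm$helix == 8L)
    for (i in seq_along(rows)) {
      coords[[rows[i]]] <- c(x = SNAKE_MARGIN + 6L * SNAKE_DX + (i - 1L) * (2L * SNAKE_R + 6L),
                             y = y8)
    }
  }
  pm$x <- vapply(coords, `[[`, numeric(1L), "x")
  pm$y <- vapply(coords, `[[`, numeric(1L), "y")
  pm
}

# Frequency of a specific residue among the gap-free residues of a column
# (0 when the residue is a gap or the column is all-gap).
residue_freq <- function(aln, column, residue) {
  col <- aln$matrix[, column]
  col <- col[col != GAP_CHAR]
  if (length(col) == 0L || residue == GAP_CHAR) {
    return(0)
  }
  sum(col == residue) / length(col)
}

svg_glyph <- function(x, y, label, letter, fill, stroke, letter_color) {
  paste0(
    sprintf('  <g class="glyph" data-label="%s">\n', label),
    sprintf('    <circle cx="%g" cy="%g" r="%g" fill="%s" stroke="%s" stroke-width="2.5"/>\n',
            x, y, SNAKE_R, fill, stroke),
    sprintf('    <text x="%g" y="%g" text-anchor="middle" font-size="10" font-family="monospace" fill="%s">%s</text>\n',
            x, y + 3.5, letter_color, letter),
    "  </g>\n"
  )
}

svg_document <- function(body, width, height) {
  doc <- paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    sprintf('<svg xmlns="http://www.w3.org/2000/svg" version="1.1" width="%g" height="%g">\n',
            width, height),
    body,
    "</svg>\n"
  )
  structure(doc, class = c("gpcr_snakeplot", "character"))
}

#' @export
print.gpcr_snakeplot <- function(x, ...) {
  n <- length(gregexpr('class="glyph"', x, fixed = TRUE)[[1L]])
  cat(sprintf("<gpcr_snakeplot> SVG document, %d glyphs\n", n))
  invisible(x)
}

#' Write a snake-plot SVG to a file
#' @param svg A `gpcr_snakeplot`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_svg <- function(svg, path) {
  stopifnot(inherits(svg, "gpcr_snakeplot"))
  writeLines(svg, path, sep = "")
  invisible(path)
}

snake_render <- function(rows, layout) {
  # loop connectors between consecutive helices (straight lines between
  # the chain ends), drawn under the glyphs
  body <- ""
  helices <- unique(layout$helix)
  for (idx in seq_along(helices)[-1L]) {
    prev <- layout[layout$helix == helices[idx - 1L], , drop = FALSE]
    cur <- layout[layout$helix == helices[idx], , drop = FALSE]
    body <- paste0(body, sprintf(
      '  <line class="loop" x1="%g" y1="%g" x2="%g" y2="%g" stroke="#BBBBBB" stroke-width="1.5"/>\n',
      prev$x[nrow(prev)], prev$y[nrow(prev)], cur$x[1L], cur$y[1L]))
  }
  body <- paste0(body, paste(rows, collapse = ""))
  svg_document(body,
               width = max(layout$x) + SNAKE_MARGIN,
               height = max(layout$y) + SNAKE_MARGIN)
}

#' Snake plot of the consensus sequence of a selection
#'
#' One glyph per mapped generic position showing the selection's consensus
#' residue; the letter's gray level encodes that residue's frequency in
#' the reference class set and the circle outline's blue level its
#' frequency in the selection itself.
#'
#' @param aln The selected `gpcr_alignment` (the group being displayed).
#' @param class_set Reference `gpcr_alignment` for the gray channel,
#'   normally the whole class; must contain every sequence of `aln`.
#'   Defaults to `aln`.
#' @return A `gpcr_snakeplot` (SVG 1.1 text). See [write_svg()].
#' @examples
#' aln <- default_fixture(seed = 1)
#' amine <- select_receptors(aln, gpcr_class = "A", scheme = "fredriksson",
#'                           path = "alpha/amine")
#' plot <- snakeplot_consensus(amine, select_receptors(aln, gpcr_class = "A"))
#' @export
snakeplot_consensus <- function(aln, class_set = aln) {
  stopifnot(inherits(aln, "gpcr_alignment"), inherits(class_set, "gpcr_alignment"))
  if (!all(names(aln$sequences) %in% names(class_set$sequences))) {
    gpcr_error("gpcr_consistency_error",
               "class_set must contain every sequence of the selection")
  }
  cons <- consensus_sequence(aln)
  layout <- snake_layout(aln$position_map)
  rows <- vapply(seq_len(nrow(layout)), function(r) {
    col <- layout$column[r]
    letter <- cons$residue[cons$column == col]
    svg_glyph(layout$x[r], layout$y[r], layout$label[r], letter,
              fill = "#FFFFFF",
              stroke = blue_shade(residue_freq(aln, col, letter)),
              letter_color = gray_shade(residue_freq(class_set, col, letter)))
  }, character(1L))
  snake_render(rows, layout)
}

#' Snake plot of a single receptor
#'
#' Glyphs show the receptor's own residues; positions where the receptor
#' is gapped are omitted. Residues that differ from the selection's
#' consensus are filled green; gray/blue channels are as in
#' [snakeplot_consensus()].
#'
#' @param entry_name Entry name of the receptor, present in `aln`.
#' @param aln The selected `gpcr_alignment` providing the consensus and
#'   the blue channel.
#' @param class_set Reference set for the gray channel (default `aln`).
#' @return A `gpcr_snakeplot`.
#' @export
snakeplot_receptor <- function(entry_name, aln, class_set = aln) {
  stopifnot(inherits(aln, "gpcr_alignment"))
  if (!entry_name %in% rownames(aln$matrix)) {
    gpcr_error("gpcr_not_found", "receptor '%s' is not in the selection", entry_name)
  }
  if (!all(names(aln$sequences) %in% names(class_set$sequences))) {
    gpcr_error("gpcr_consistency_error",
               "class_set must contain every sequence of the selection")
  }
  cons <- consensus_sequence(aln)
  layout <- snake_layout(aln$position_map)
  residues <- aln$matrix[entry_name, ]
  keep <- residues[layout$column] != GAP_CHAR
  rows <- vapply(which(keep), function(r) {
    col <- layout$column[r]
    letter <- residues[col]
    mismatch <- letter != cons$residue[cons$column == col]
    svg_glyph(layout$x[r], layout$y[r], layout$label[r], letter,
              fill = if (mismatch) "#7CCD7C" else "#FFFFFF",
              stroke = blue_shade(residue_freq(aln, col, letter)),
              letter_color = gray_shade(residue_freq(class_set, col, letter)))
  }, character(1L))
  snake_render(rows, layout[keep, , drop = FALSE])
}
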