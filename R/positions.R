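# Generic-position specifications: single Ballesteros-Weinstein labels
# ("3.50"), consecutive ranges within one helix ("3.50-3.54"), or
# comma-separated lists mixing both ("3.50,4.50,5.50").

LABEL_RX <- "^[1-8]\\.[0-9]{1,2}$"

parse_label <- function(label) {
  if (!grepl(LABEL_RX, label)) {
    gpcr_error("gpcr_position_error", "malformed generic position label '%s'", label)
  }
  parts <- strsplit(label, ".", fixed = TRUE)[[1L]]
  list(label = label, helix = as.integer(parts[1L]), index = as.integer(parts[2L]))
}

#' Parse a generic position specification
#'
#' A specification is a comma-separated list of single generic position
#' labels (`"3.50"`) and/or ranges (`"3.50-3.54"`). Ranges must stay within
#' one helix and expand, against a position map, to every mapped label with
#' an index between the two endpoints inclusive. An en dash is accepted as
#' a range separator.
#'
#' @param text Specification string, e.g. `"3.40,5.50,6.44"`.
#' @return A `gpcr_positions` object. `format()` reproduces a canonical
#'   form such that `parse_positions(format(x))` equals `x`.
#' @examples
#' parse_positions("3.50-3.52")
#' parse_positions("3.40, 5.50, 6.44")
#' @export
parse_positions <- function(text) {
  if (inherits(text, "gpcr_positions")) {
    return(text)
  }
  stopifnot(is.character(text), length(text) == 1L)
  text <- gsub("–", "-", text)          # en dash -> hyphen
  raw_items <- trimws(strsplit(text, ",", fixed = TRUE)[[1L]])
  raw_items <- raw_items[nzchar(raw_items)]
  if (length(raw_items) == 0L) {
    gpcr_error("gpcr_position_error", "empty position specification")
  }
  items <- lapply(raw_items, function(it) {
    if (grepl("-", it, fixed = TRUE)) {
      ends <- trimws(strsplit(it, "-", fixed = TRUE)[[1L]])
      if (length(ends) != 2L) {
        gpcr_error("gpcr_position_error", "malformed range '%s'", it)
      }
      from <- parse_label(ends[1L])
      to <- parse_label(ends[2L])
      if (from$helix != to$helix) {
        gpcr_error("gpcr_range_error",
                   "range '%s' spans helices %d and %d", it, from$helix, to$helix)
      }
      if (from$index > to$index) {
        gpcr_error("gpcr_range_error", "range '%s' is reversed", it)
      }
      list(type = "range", from = from, to = to)
    } else {
      list(type = "single", at = parse_label(it))
    }
  })
  structure(list(items = items), class = "gpcr_positions")
}

#' @export
format.gpcr_positions <- function(x, ...) {
  paste(vapply(x$items, function(it) {
    if (it$type == "single") it$at$label
    else paste0(it$from$label, "-", it$to$label)
  }, character(1L)), collapse = ",")
}

#' @export
print.gpcr_positions <- function(x, ...) {
  cat("<gpcr_positions> ", format(x), "\n", sep = "")
  invisible(x)
}

# Resolve a specification against a position map, returning a data frame
# with one row per expanded position (column = 1-based alignment column,
# label) in specification order.
resolve_positions <- function(posmap, positions) {
  spec <- parse_positions(positions)
  out <- lapply(spec$items, function(it) {
    if (it$type == "single") {
      hit <- match(it$at$label, posmap$label)
      if (is.na(hit)) {
        gpcr_error("gpcr_position_error",
                   "generic position '%s' is not in the position map", it$at$label)
      }
      posmap[hit, c("column", "label")]
    } else {
      for (end in c(it$from$label, it$to$label)) {
        if (!end %in% posmap$label) {
          gpcr_error("gpcr_position_error",
                     "generic position '%s' is not in the position map", end)
        }
      }
      sel <- posmap$helix == it$from$helix &
        posmap$index >= it$from$index & posmap$index <= it$to$index
      rows <- posmap[sel, , drop = FALSE]
      rows <- rows[order(rows$index), c("column", "label")]
      rows
    }
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Alignment columns for a generic position specification
#'
#' Translates generic position labels to alignment column indices through
#' the alignment's position map, preserving the order in which positions
#' are written. Ranges expand to every mapped label between their endpoints
#' within the helix.
#'
#' @param x A `gpcr_alignment` (or its position-map data frame).
#' @param positions A specification string or `gpcr_positions` object.
#' @return Integer vector of alignment columns (1-based).
#' @export
columns_for <- function(x, positions) {
  posmap <- if (inherits(x, "gpcr_alignment")) x$position_map else x
  resolve_positions(posmap, positions)$column
}
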