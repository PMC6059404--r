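# Association (correlation) between two motifs at two position sets:
# 2x2 presence/absence contingency tables, odds ratios with Woolf
# (log-method) 95% confidence intervals, Haldane-Anscombe zero-cell
# correction, and per-category same-level / sub-level output.

#' Build a 2x2 contingency table directly from cell counts
#'
#' Cells follow the usual layout: `a` = both motifs present, `b` = first
#' present only, `c` = second present only, `d` = both absent.
#'
#' @param a,b,c,d Non-negative integer counts.
#' @return A `gpcr_contingency`.
#' @examples
#' odds_ratio(contingency_table(14, 3, 1, 4))
#' @export
contingency_table <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  stopifnot(all(cells >= 0), all(cells == floor(cells)))
  structure(list(a = a, b = b, c = c, d = d, n = sum(cells)),
            class = "gpcr_contingency")
}

#' @export
print.gpcr_contingency <- function(x, ...) {
  cat(sprintf("2x2 table (n = %d): a=%d b=%d c=%d d=%d\n",
              x$n, x$a, x$b, x$c, x$d))
  invisible(x)
}

#' Cross-tabulate presence/absence of two motifs
#'
#' Each sequence gap-free at both position sets contributes to exactly one
#' cell of the 2x2 table according to whether it matches motif 1 and/or
#' motif 2; gapped sequences are excluded entirely.
#'
#' @param aln A `gpcr_alignment`.
#' @param positions1,positions2 Position specifications.
#' @param motif1,motif2 Motif patterns (strings or `gpcr_motif`).
#' @return A `gpcr_contingency`.
#' @export
contingency <- function(aln, positions1, motif1, positions2, motif2) {
  m1 <- motif_matches(motif1, aln, columns_for(aln, positions1))
  m2 <- motif_matches(motif2, aln, columns_for(aln, positions2))
  keep <- !is.na(m1) & !is.na(m2)
  if (!any(keep)) {
    gpcr_error("gpcr_empty_denominator",
               "no sequence is gap-free at both position sets")
  }
  m1 <- m1[keep]
  m2 <- m2[keep]
  contingency_table(sum(m1 & m2), sum(m1 & !m2), sum(!m1 & m2), sum(!m1 & !m2))
}

#' Odds ratio with Woolf 95% confidence interval
#'
#' `OR = (a*d)/(b*c)` with the log-method interval
#' `exp(ln OR +- 1.96 * sqrt(1/a + 1/b + 1/c + 1/d))`. If any cell is
#' zero, the Haldane-Anscombe correction adds 0.5 to all four cells first
#' and the result is flagged `corrected`. A table with an entirely zero
#' margin (a row or column of the 2x2) has no defined association and is
#' an error.
#'
#' @param ct A `gpcr_contingency` from [contingency()] or
#'   [contingency_table()].
#' @param conf_z Normal quantile for the interval (default 1.96, i.e. 95%).
#' @return A `gpcr_oddsratio`: list with `oddsratio`, `ci_low`, `ci_high`,
#'   `corrected` and the (possibly corrected) `cells`. Printed at display
#'   precision (OR to 2 decimals; CI bounds to 2 decimals, or 1 above 100).
#' @examples
#' odds_ratio(contingency_table(14, 3, 1, 4))   # OR 18.67, CI 1.50-232.3
#' @export
odds_ratio <- function(ct, conf_z = 1.96) {
  stopifnot(inherits(ct, "gpcr_contingency"))
  raw <- c(a = ct$a, b = ct$b, c = ct$c, d = ct$d)
  if ((raw["a"] + raw["b"]) == 0 || (raw["c"] + raw["d"]) == 0 ||
      (raw["a"] + raw["c"]) == 0 || (raw["b"] + raw["d"]) == 0) {
    gpcr_error("gpcr_undefined_association",
               "a margin of the 2x2 table is entirely zero")
  }
  corrected <- any(raw == 0)
  cells <- if (corrected) raw + 0.5 else raw
  or <- (cells[["a"]] * cells[["d"]]) / (cells[["b"]] * cells[["c"]])
  se <- sqrt(sum(1 / cells))
  ci <- exp(log(or) + c(-1, 1) * conf_z * se)
  structure(
    list(oddsratio = or, ci_low = ci[1L], ci_high = ci[2L],
         corrected = corrected, cells = cells, n = ct$n),
    class = "gpcr_oddsratio"
  )
}

# Display precision: 2 decimals below 100, 1 above (the interval's upper
# bound is often large).
format_or_value <- function(x) {
  if (x >= 100) sprintf("%.1f", x) else sprintf("%.2f", x)
}

#' @export
print.gpcr_oddsratio <- function(x, ...) {
  cat(sprintf("odds ratio %s (95%% CI %s to %s)%s\n",
              format_or_value(x$oddsratio), format_or_value(x$ci_low),
              format_or_value(x$ci_high),
              if (x$corrected) " [Haldane-Anscombe corrected]" else ""))
  invisible(x)
}

#' Motif association for a selection and its sibling/child categories
#'
#' Computes the 2x2 table and odds ratio for the selection named by the
#' classification filter, then repeats the identical analysis in every
#' same-level (sibling) and sub-level (child) category. Categories whose
#' tables are degenerate (empty selection, all-gapped, zero margin) are
#' reported with status `"undefined"` rather than dropped.
#'
#' @inheritParams contingency
#' @param gpcr_class,taxon,scheme,path,include_olfactory Selection naming
#'   the classification node, as in [select_receptors()].
#' @return A `gpcr_correlation`: list with `overall` (the selection's
#'   `gpcr_oddsratio`) and `levels`, a data frame with one row per
#'   category (`level`, `category`, cells, `oddsratio`, `ci_low`,
#'   `ci_high`, `corrected`, `status`).
#' @export
correlate_with_levels <- function(aln, positions1, motif1, positions2, motif2,
                                  gpcr_class = NULL, taxon = "All",
                                  scheme = NULL, path = NULL,
                                  include_olfactory = FALSE) {
  sel <- select_receptors(aln, gpcr_class = gpcr_class, taxon = taxon,
                          scheme = scheme, path = path,
                          include_olfactory = include_olfactory)
  overall <- odds_ratio(contingency(sel, positions1, motif1, positions2, motif2))
  cats <- level_categories(aln, gpcr_class = gpcr_class, taxon = taxon,
                           scheme = scheme, path = path,
                           include_olfactory = include_olfactory)
  rows <- lapply(cats, function(ctg) {
    res <- tryCatch({
      s <- do.call(select_receptors, c(list(aln), ctg$args))
      tab <- contingency(s, positions1, motif1, positions2, motif2)
      list(tab = tab, or = odds_ratio(tab))
    }, gpcralign_error = function(e) NULL)
    if (is.null(res)) {
      data.frame(level = ctg$level, category = ctg$category,
                 a = NA_integer_, b = NA_integer_, c = NA_integer_,
                 d = NA_integer_, oddsratio = NA_real_, ci_low = NA_real_,
                 ci_high = NA_real_, corrected = NA,
                 status = "undefined", stringsAsFactors = FALSE)
    } else {
      data.frame(level = ctg$level, category = ctg$category,
                 a = res$tab$a, b = res$tab$b, c = res$tab$c, d = res$tab$d,
                 oddsratio = res$or$oddsratio, ci_low = res$or$ci_low,
                 ci_high = res$or$ci_high, corrected = res$or$corrected,
                 status = "ok", stringsAsFactors = FALSE)
    }
  })
  levels_df <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame(level = character(), category = character(),
               a = integer(), b = integer(), c = integer(), d = integer(),
               oddsratio = numeric(), ci_low = numeric(),
               ci_high = numeric(), corrected = logical(),
               status = character(), stringsAsFactors = FALSE)
  structure(list(overall = overall, levels = levels_df),
            class = "gpcr_correlation")
}

#' @export
print.gpcr_correlation <- function(x, ...) {
  cat("Selection: ")
  print(x$overall)
  if (nrow(x$levels) > 0L) {
    cat("Categories:\n")
    print(x$levels, row.names = FALSE)
  }
  invisible(x)
}
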