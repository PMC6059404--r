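# Covariation between two positions (or position lists): OMES (observed
# minus expected squared), mutual information (natural log), and the
# average-product-corrected MIp, with Z-scores and one-sided p-values
# against the background of all unordered single-column pairs of the
# selection.

#' Joint residue-pair distribution for two position sets
#'
#' Tabulates observed pair counts over the sequences gap-free at *both*
#' position sets, together with the marginal distributions computed on
#' that same jointly gap-free subset and the independence expectations
#' `N * p_x(i) * p_y(j)` (so observed and expected counts both sum to N).
#'
#' @param aln A `gpcr_alignment`.
#' @param positions_i,positions_j Position specifications; multi-position
#'   specs are treated as joint tuple symbols.
#' @return A `gpcr_pairdist`: list with `n_pairs` (N), `observed` and
#'   `expected` count matrices (rows = symbols at i, columns = symbols at
#'   j), marginal probabilities `p_i`, `p_j`, and the expanded labels.
#' @export
pair_distribution <- function(aln, positions_i, positions_j) {
  stopifnot(inherits(aln, "gpcr_alignment"))
  res_i <- resolve_positions(aln$position_map, positions_i)
  res_j <- resolve_positions(aln$position_map, positions_j)
  sub_i <- aln$matrix[, res_i$column, drop = FALSE]
  sub_j <- aln$matrix[, res_j$column, drop = FALSE]
  gap_free <- rowSums(sub_i == GAP_CHAR) == 0L & rowSums(sub_j == GAP_CHAR) == 0L
  if (!any(gap_free)) {
    gpcr_error("gpcr_empty_denominator",
               "no sequence is gap-free at both position sets")
  }
  ti <- apply(sub_i[gap_free, , drop = FALSE], 1L, paste, collapse = "")
  tj <- apply(sub_j[gap_free, , drop = FALSE], 1L, paste, collapse = "")
  obs <- table(ti, tj)
  N <- sum(gap_free)
  obs <- matrix(as.numeric(obs), nrow = nrow(obs),
                dimnames = dimnames(obs))
  p_i <- rowSums(obs) / N
  p_j <- colSums(obs) / N
  expected <- N * outer(p_i, p_j)
  structure(
    list(n_pairs = N, observed = obs, expected = expected,
         p_i = p_i, p_j = p_j,
         labels_i = res_i$label, labels_j = res_j$label),
    class = "gpcr_pairdist"
  )
}

#' OMES covariation score
#'
#' Observed minus expected squared:
#' `OMES(i,j) = (1/N) * sum_{x,y} (N_obs(x,y) - N_exp(x,y))^2`, with N the
#' number of sequences gap-free at both positions and the sum over every
#' residue pair with a positive observed or expected count. Zero when the
#' two positions are independent or either is invariant.
#'
#' @param pd A `gpcr_pairdist` from [pair_distribution()].
#' @return Non-negative numeric score, symmetric in the two positions.
#' @export
omes <- function(pd) {
  stopifnot(inherits(pd, "gpcr_pairdist"))
  sum((pd$observed - pd$expected)^2) / pd$n_pairs
}

#' Mutual information between two position sets (nats)
#'
#' `MI(i,j) = sum_{x,y} p_xy * ln(p_xy / (p_x * p_y))` over observed
#' residue pairs, natural logarithm; zero-probability terms contribute
#' zero. For identical columns with k uniform symbols MI equals `ln k`.
#'
#' @param pd A `gpcr_pairdist` from [pair_distribution()].
#' @return Non-negative numeric score in nats, symmetric in the positions.
#' @export
mutual_information <- function(pd) {
  stopifnot(inherits(pd, "gpcr_pairdist"))
  p_xy <- pd$observed / pd$n_pairs
  ratio <- p_xy / outer(pd$p_i, pd$p_j)
  pos <- p_xy > 0
  sum(p_xy[pos] * log(ratio[pos]))
}

# OMES and MI for every unordered pair of single alignment columns, in one
# pass; cached on the alignment (the background is O(L^2) in columns and
# reused by every Z-score).
background_pair_stats <- function(aln, columns = NULL) {
  if (is.null(columns)) columns <- aln$position_map$column
  key <- paste0("bg:", paste(columns, collapse = ","))
  if (!is.null(aln$cache[[key]])) {
    return(aln$cache[[key]])
  }
  L <- length(columns)
  m <- aln$matrix[, columns, drop = FALSE]
  gaps <- m == GAP_CHAR
  omes_m <- matrix(0, L, L)
  mi_m <- matrix(0, L, L)
  for (a in seq_len(L - 1L)) {
    for (b in seq(a + 1L, L)) {
      gf <- !gaps[, a] & !gaps[, b]
      N <- sum(gf)
      if (N == 0L) next
      obs <- table(m[gf, a], m[gf, b])
      obs <- matrix(as.numeric(obs), nrow = nrow(obs), dimnames = dimnames(obs))
      p_i <- rowSums(obs) / N
      p_j <- colSums(obs) / N
      expd <- N * outer(p_i, p_j)
      omes_m[a, b] <- omes_m[b, a] <- sum((obs - expd)^2) / N
      p_xy <- obs / N
      pos <- p_xy > 0
      mi_m[a, b] <- mi_m[b, a] <-
        sum(p_xy[pos] * log((p_xy / outer(p_i, p_j))[pos]))
    }
  }
  out <- list(columns = columns, omes = omes_m, mi = mi_m)
  aln$cache[[key]] <- out
  out
}

# Average-product correction over a symmetric MI matrix (diag ignored).
apc_matrix <- function(M) {
  n <- nrow(M)
  diag(M) <- 0
  row_mean <- rowSums(M) / (n - 1L)
  mi_mean <- sum(M[upper.tri(M)]) / (n * (n - 1L) / 2)
  if (mi_mean == 0) {
    gpcr_error("gpcr_degenerate_background",
               "mean background MI is zero; MIp is undefined")
  }
  M - outer(row_mean, row_mean) / mi_mean
}

#' Average-product-corrected mutual information (MIp)
#'
#' `MIp(i,j) = MI(i,j) - MI(i,.) * MI(.,j) / MI_mean`, where `MI(i,.)` is
#' the mean MI of position i against every other background column,
#' `MI(.,j)` likewise for j, and `MI_mean` the mean over all unordered
#' background column pairs. The correction removes the shared-entropy and
#' phylogenetic background: a uniform background cancels exactly to 0.
#' May be negative.
#'
#' @inheritParams pair_distribution
#' @param background_columns Alignment columns forming the background
#'   (default: every mapped column). At least 3, including the target
#'   columns.
#' @return Numeric MIp score.
#' @export
mip <- function(aln, positions_i, positions_j, background_columns = NULL) {
  stopifnot(inherits(aln, "gpcr_alignment"))
  if (is.null(background_columns)) background_columns <- aln$position_map$column
  n <- length(background_columns)
  if (n < 3L) {
    gpcr_error("gpcr_degenerate_background",
               "MIp needs a background of at least 3 columns")
  }
  cols_i <- columns_for(aln, positions_i)
  cols_j <- columns_for(aln, positions_j)
  bg <- background_pair_stats(aln, background_columns)
  M <- bg$mi
  diag(M) <- 0
  mi_mean <- sum(M[upper.tri(M)]) / (n * (n - 1L) / 2)
  if (mi_mean == 0) {
    gpcr_error("gpcr_degenerate_background",
               "mean background MI is zero; MIp is undefined")
  }
  mi_dot <- function(cols) {
    others <- setdiff(background_columns, cols)
    if (length(cols) == 1L && cols %in% background_columns) {
      idx <- match(cols, background_columns)
      sum(M[idx, ]) / (n - 1L)
    } else {
      mean(vapply(others, function(cc) {
        mutual_information(pair_distribution(
          aln, aln$position_map$label[match(cols, aln$position_map$column)] |>
            paste(collapse = ","),
          aln$position_map$label[match(cc, aln$position_map$column)]))
      }, numeric(1L)))
    }
  }
  mi_ij <- mutual_information(pair_distribution(aln, positions_i, positions_j))
  mi_ij - mi_dot(cols_i) * mi_dot(cols_j) / mi_mean
}

#' Z-score and one-sided p-value of a score against a background
#'
#' `z = (score - mean) / sd` over the background scores (all unordered
#' position pairs; sample standard deviation), with the one-sided
#' upper-tail standard-normal probability `p = P(Z > z)` — high scores
#' mean covariation.
#'
#' @param scores Numeric vector of background scores (length >= 3), one
#'   per unordered pair; may be named.
#' @param target The target pair's score (numeric), or the name of an
#'   element of `scores`.
#' @return List with `z` and `p`.
#' @examples
#' z_and_p(c(0, 0, 0, 3), 3)
#' @export
z_and_p <- function(scores, target) {
  if (is.character(target)) {
    stopifnot(target %in% names(scores))
    target <- scores[[target]]
  }
  if (length(scores) < 3L) {
    gpcr_error("gpcr_degenerate_background",
               "need at least 3 background pairs for a Z-score")
  }
  s <- stats::sd(scores)
  if (!is.finite(s) || s == 0) {
    gpcr_error("gpcr_degenerate_background",
               "background standard deviation is zero")
  }
  z <- (target - mean(scores)) / s
  list(z = z, p = stats::pnorm(z, lower.tail = FALSE))
}

#' Full covariation analysis of two positions
#'
#' Computes OMES, MI and MIp for the pair, then Z-scores and one-sided
#' p-values by comparison with the same score computed for every unordered
#' pair of single mapped columns of the selection (the all-pairs
#' background), using the same joint gap policy throughout.
#'
#' @inheritParams pair_distribution
#' @return A `gpcr_covariance`: list with `n_pairs`, `omes`, `mi`, `mip`,
#'   `z_omes`, `p_omes`, `z_mip`, `p_mip` and `n_background_pairs`.
#' @examples
#' aln <- default_fixture(seed = 1)
#' cset <- select_receptors(aln, gpcr_class = "C", taxon = "All")
#' covary(cset, "3.40", "6.44")
#' @export
covary <- function(aln, positions_i, positions_j) {
  pd <- pair_distribution(aln, positions_i, positions_j)
  bg <- background_pair_stats(aln)
  up <- upper.tri(bg$omes)
  omes_scores <- bg$omes[up]
  mip_all <- apc_matrix(bg$mi)
  mip_scores <- mip_all[up]

  omes_v <- omes(pd)
  mi_v <- mutual_information(pd)
  mip_v <- mip(aln, positions_i, positions_j)
  zo <- z_and_p(omes_scores, omes_v)
  zm <- z_and_p(mip_scores, mip_v)
  structure(
    list(positions_i = format(parse_positions(positions_i)),
         positions_j = format(parse_positions(positions_j)),
         n_pairs = pd$n_pairs, omes = omes_v, mi = mi_v, mip = mip_v,
         z_omes = zo$z, p_omes = zo$p, z_mip = zm$z, p_mip = zm$p,
         n_background_pairs = length(omes_scores)),
    class = "gpcr_covariance"
  )
}

#' @export
print.gpcr_covariance <- function(x, ...) {
  cat(sprintf("Covariation %s vs %s (N = %d gap-free pairs)\n",
              x$positions_i, x$positions_j, x$n_pairs))
  cat(sprintf("  OMES = %.4f  (Z = %.2f, p = %.3g)\n", x$omes, x$z_omes, x$p_omes))
  cat(sprintf("  MI   = %.4f nats\n", x$mi))
  cat(sprintf("  MIp  = %.4f  (Z = %.2f, p = %.3g)\n", x$mip, x$z_mip, x$p_mip))
  invisible(x)
}
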