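# Independent brute-force oracles for the covariation scores and the odds
# ratio. Written as plain loops over a character matrix, sharing no code
# with the package implementations.

oracle_joint <- function(mat, cols_i, cols_j) {
  keep <- logical(nrow(mat))
  ti <- tj <- character(nrow(mat))
  for (r in seq_len(nrow(mat))) {
    ri <- mat[r, cols_i]
    rj <- mat[r, cols_j]
    if (any(ri == "-") || any(rj == "-")) next
    keep[r] <- TRUE
    ti[r] <- paste(ri, collapse = "")
    tj[r] <- paste(rj, collapse = "")
  }
  list(ti = ti[keep], tj = tj[keep], N = sum(keep))
}

oracle_omes <- function(mat, cols_i, cols_j) {
  jt <- oracle_joint(mat, cols_i, cols_j)
  total <- 0
  for (x in unique(jt$ti)) {
    for (y in unique(jt$tj)) {
      n_obs <- 0
      for (r in seq_len(jt$N)) {
        if (jt$ti[r] == x && jt$tj[r] == y) n_obs <- n_obs + 1
      }
      n_exp <- jt$N * (sum(jt$ti == x) / jt$N) * (sum(jt$tj == y) / jt$N)
      total <- total + (n_obs - n_exp)^2
    }
  }
  total / jt$N
}

oracle_mi <- function(mat, cols_i, cols_j) {
  jt <- oracle_joint(mat, cols_i, cols_j)
  total <- 0
  for (x in unique(jt$ti)) {
    for (y in unique(jt$tj)) {
      p_xy <- sum(jt$ti == x & jt$tj == y) / jt$N
      if (p_xy > 0) {
        p_x <- sum(jt$ti == x) / jt$N
        p_y <- sum(jt$tj == y) / jt$N
        total <- total + p_xy * log(p_xy / (p_x * p_y))
      }
    }
  }
  total
}

# Average-product-corrected MI for single columns i, j against a
# background column set, all by explicit sums.
oracle_mip <- function(mat, i, j, bg) {
  n <- length(bg)
  mi_i <- 0
  for (c in bg) if (c != i) mi_i <- mi_i + oracle_mi(mat, i, c)
  mi_i <- mi_i / (n - 1)
  mi_j <- 0
  for (c in bg) if (c != j) mi_j <- mi_j + oracle_mi(mat, j, c)
  mi_j <- mi_j / (n - 1)
  mi_bar <- 0
  for (a in seq_along(bg)) {
    for (b in seq_along(bg)) {
      if (a < b) mi_bar <- mi_bar + oracle_mi(mat, bg[a], bg[b])
    }
  }
  mi_bar <- mi_bar * 2 / (n * (n - 1))
  oracle_mi(mat, i, j) - mi_i * mi_j / mi_bar
}

# Unscaled column entropy in nats (for the MI upper-bound check).
oracle_h_nats <- function(mat, col) {
  v <- mat[, col]
  v <- v[v != "-"]
  p <- as.numeric(table(v)) / length(v)
  -sum(p * log(p))
}

oracle_odds_ratio <- function(a, b, c, d, z = 1.96) {
  if (a == 0 || b == 0 || c == 0 || d == 0) {
    a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5
  }
  or <- a * d / (b * c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  c(or = or, lo = exp(log(or) - z * se), hi = exp(log(or) + z * se))
}
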