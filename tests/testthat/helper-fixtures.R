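# Small in-code fixtures shared across the suite.

# A fully valid tiny stack whose elevation is given explicitly; extra layers
# can be passed as named matrices/vectors recycled to the grid shape.
tiny_stack <- function(elev, ..., island_id = "toy", cell_size = 1) {
  elev <- as.matrix(elev)
  layers <- list(elevation = grid_raster(elev, cell_size = cell_size))
  extra <- list(...)
  for (nm in names(extra)) {
    v <- matrix(rep_len(as.numeric(extra[[nm]]), length(elev)),
                nrow(elev), ncol(elev))
    v[is.na(elev)] <- NA_real_
    layers[[nm]] <- grid_raster(v, cell_size = cell_size)
  }
  env_stack(layers, island_id)
}

# A 2 x 5 ten-cell landscape with a single elevation gradient 1..10.
ten_cell_stack <- function() {
  tiny_stack(matrix(1:10, 2, 5, byrow = TRUE))
}

# Independent brute-force oracles -------------------------------------------

# Schoener's D by direct per-cell accumulation.
oracle_schoener_d <- function(a, b) {
  pa <- a / sum(a); pb <- b / sum(b)
  acc <- 0
  for (i in seq_along(pa)) acc <- acc + abs(pa[i] - pb[i])
  1 - acc / 2
}

# Spearman r as rank-then-Pearson with explicit formulas.
oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  mx <- mean(rx); my <- mean(ry)
  sum((rx - mx) * (ry - my)) /
    sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}

# Tie-corrected Kruskal-Wallis H by the textbook rank formula.
oracle_kruskal_h <- function(groups) {
  all_v <- unlist(groups)
  n <- length(all_v)
  r <- rank(all_v)
  idx <- rep(seq_along(groups), lengths(groups))
  h <- 12 / (n * (n + 1)) *
    sum(vapply(seq_along(groups), function(g) {
      ri <- r[idx == g]
      length(ri) * (mean(ri) - (n + 1) / 2)^2
    }, 1))
  ties <- table(all_v)
  h / (1 - sum(ties^3 - ties) / (n^3 - n))
}

# All-pairs Mann-Whitney AUC.
oracle_auc <- function(pos, neg) {
  wins <- 0
  for (p in pos) for (q in neg) {
    wins <- wins + (p > q) + 0.5 * (p == q)
  }
  wins / (length(pos) * length(neg))
}

# OLS coefficients from the normal equations.
oracle_ols <- function(y, X) {
  Xm <- cbind(1, as.matrix(X))
  drop(solve(t(Xm) %*% Xm, t(Xm) %*% y))
}

# AICc, delta and weights by direct formula evaluation.
oracle_aicc <- function(logLik, k, n) {
  aicc <- -2 * logLik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
  delta <- aicc - min(aicc)
  w <- exp(-delta / 2)
  list(aicc = aicc, delta = delta, weight = w / sum(w))
}
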