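# Independent brute-force oracles. These deliberately avoid the package's
# code paths (and the library shortcuts it uses) so that agreement is a real
# cross-check, not a tautology.

# textbook Pearson: covariance over the product of standard deviations,
# accumulated with explicit loops
oracle_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n
  my <- sum(y) / n
  sxy <- sxx <- syy <- 0
  for (i in seq_len(n)) {
    sxy <- sxy + (x[i] - mx) * (y[i] - my)
    sxx <- sxx + (x[i] - mx)^2
    syy <- syy + (y[i] - my)^2
  }
  sxy / sqrt(sxx * syy)
}

# elementwise mean absolute difference
oracle_mae <- function(a, b) {
  s <- 0
  for (i in seq_along(a)) s <- s + abs(a[i] - b[i])
  s / length(a)
}

# per-column min-max rescaling by explicit loop
oracle_minmax <- function(x) {
  out <- x
  for (j in seq_len(ncol(x))) {
    lo <- min(x[, j]); hi <- max(x[, j])
    out[, j] <- (x[, j] - lo) / (hi - lo)
  }
  out
}

# closed-form simple OLS of y on x
oracle_ols <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  slope <- sum((x - mx) * (y - my)) / sum((x - mx)^2)
  intercept <- my - slope * mx
  yhat <- intercept + slope * x
  r2 <- 1 - sum((y - yhat)^2) / sum((y - my)^2)
  list(slope = slope, intercept = intercept, r_squared = r2)
}

# PCA by eigendecomposition of the hand-accumulated covariance matrix;
# returns loadings (k columns), scores and per-component variance fractions
oracle_pca <- function(x, k) {
  n <- nrow(x); p <- ncol(x)
  mu <- colSums(x) / n
  xc <- sweep(x, 2, mu)
  cv <- matrix(0, p, p)
  for (i in seq_len(n)) cv <- cv + tcrossprod(xc[i, ])
  cv <- cv / (n - 1)
  eg <- eigen(cv, symmetric = TRUE)
  list(loadings = eg$vectors[, seq_len(k), drop = FALSE],
       scores = xc %*% eg$vectors[, seq_len(k), drop = FALSE],
       vaf = eg$values / sum(eg$values))
}

# interval intersection by brute force over a fine time grid
oracle_overlap <- function(a_range, b_range, grid_step = 1e-3) {
  g <- seq(min(a_range[1], b_range[1]), max(a_range[2], b_range[2]),
           by = grid_step)
  inside <- g[g >= a_range[1] & g <= a_range[2] &
              g >= b_range[1] & g <= b_range[2]]
  range(inside)
}
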