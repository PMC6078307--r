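# Independent oracles and graph builders used across the test files. These
# deliberately re-derive quantities by a different route than the package
# (explicit normal equations, manual step-up, exhaustive reachability).

# Partial Spearman by explicit arithmetic: average ranks, OLS residuals via
# the normal equations, then a hand-written Pearson correlation.
oracle_partial_spearman <- function(x, y, covariates) {
  covariates <- as.data.frame(covariates)
  cc <- stats::complete.cases(x, y, covariates)
  x <- x[cc]
  y <- y[cc]
  covariates <- covariates[cc, , drop = FALSE]
  rx <- rank(x)
  ry <- rank(y)
  X <- cbind(1, vapply(covariates, rank, numeric(length(x))))
  bx <- solve(t(X) %*% X, t(X) %*% rx)
  by <- solve(t(X) %*% X, t(X) %*% ry)
  ex <- as.numeric(rx - X %*% bx)
  ey <- as.numeric(ry - X %*% by)
  ex <- ex - mean(ex)
  ey <- ey - mean(ey)
  sum(ex * ey) / sqrt(sum(ex^2) * sum(ey^2))
}

# Benjamini-Hochberg step-up written out directly.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- pmin(rev(cummin(rev(q))), 1)
  out <- numeric(m)
  out[o] <- q
  out
}

bfs_connected <- function(W) {
  n <- nrow(W)
  seen <- logical(n)
  seen[1] <- TRUE
  frontier <- 1L
  while (length(frontier)) {
    nxt <- which(colSums(W[frontier, , drop = FALSE] > 0) > 0 & !seen)
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  all(seen)
}

rand_connected_graph <- function(n, p_edge = 0.6, wmin = 0.3, wmax = 1) {
  repeat {
    W <- matrix(0, n, n)
    ut <- upper.tri(W)
    m <- sum(ut)
    present <- stats::runif(m) < p_edge
    W[ut] <- ifelse(present, stats::runif(m, wmin, wmax), 0)
    W <- W + t(W)
    if (bfs_connected(W)) return(W)
  }
}

star_graph <- function(n_leaves, w = 1) {
  W <- matrix(0, n_leaves + 1, n_leaves + 1)
  W[1, -1] <- W[-1, 1] <- w
  W
}

path_graph <- function(n, w = 1) {
  W <- matrix(0, n, n)
  for (i in seq_len(n - 1)) W[i, i + 1] <- W[i + 1, i] <- w
  W
}

# Two region signals with an exact sample correlation r.
pair_with_cor <- function(r, t = 64) {
  x <- stats::rnorm(t)
  e <- stats::rnorm(t)
  x <- x - mean(x)
  x <- x / sqrt(sum(x^2))
  e <- e - mean(e)
  e <- e - sum(e * x) * x
  e <- e / sqrt(sum(e^2))
  y <- r * x + sqrt(1 - r^2) * e
  cbind(A = x, B = y)
}

# Tiny cohort spec for fast end-to-end runs.
tiny_spec <- function(seed = 1, ...) {
  cohort_spec(n_subjects = 10, n_male = 5, yfas_completion = 8,
              n_regions = 16, t_points = 40, seed = seed, ...)
}
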