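# Independent oracles, deliberately written as naive reference
# implementations so they share no code path with the package.

# Accordance/discordance by an explicit per-timepoint double loop.
brute_accordance_discordance <- function(z, q) {
  Tn <- nrow(z)
  R <- ncol(z)
  hi <- qnorm(q)
  lo <- qnorm(1 - q)
  u <- matrix(0, Tn, R)
  l <- matrix(0, Tn, R)
  for (t in seq_len(Tn)) {
    for (r in seq_len(R)) {
      if (z[t, r] >= hi) u[t, r] <- 1
      if (z[t, r] <= lo) l[t, r] <- 1
    }
  }
  sig <- numeric(R)
  for (r in seq_len(R)) {
    acc <- 0
    for (t in seq_len(Tn)) acc <- acc + u[t, r] * u[t, r] + l[t, r] * l[t, r]
    sig[r] <- sqrt(acc)
  }
  a <- matrix(0, R, R)
  d <- matrix(0, R, R)
  for (i in seq_len(R)) {
    for (j in seq_len(R)) {
      na <- 0
      nd <- 0
      for (t in seq_len(Tn)) {
        na <- na + u[t, i] * u[t, j] + l[t, i] * l[t, j]
        nd <- nd + u[t, i] * l[t, j] + l[t, i] * u[t, j]
      }
      a[i, j] <- na / (sig[i] * sig[j])
      d[i, j] <- nd / (sig[i] * sig[j])
    }
  }
  list(a = a, d = d)
}

# Single-component PLS by iterative NIPALS on centered data.
nipals_pls1 <- function(X, y, tol = 1e-12, max_iter = 500) {
  Xc <- scale(X, scale = FALSE)
  yc <- y - mean(y)
  u <- yc
  w_old <- rep(Inf, ncol(Xc))
  for (iter in seq_len(max_iter)) {
    w <- drop(crossprod(Xc, u)) / sum(u^2)
    w <- w / sqrt(sum(w^2))
    tt <- drop(Xc %*% w)
    cc <- sum(tt * yc) / sum(tt^2)
    u <- yc * cc
    if (sum((w - w_old)^2) < tol) break
    w_old <- w
  }
  fitted <- mean(y) + tt * cc
  list(fitted = fitted, weights = w, loading = cc)
}

# Partial correlation by explicit residualization.
residualized_partial_cor <- function(x, y, z) {
  rx <- residuals(lm(x ~ z))
  ry <- residuals(lm(y ~ z))
  cor(rx, ry)
}

# Multivariate normal draws via Cholesky (for Steiger calibration).
rmvnorm_chol <- function(n, sigma) {
  L <- chol(sigma)
  matrix(rnorm(n * ncol(sigma)), n) %*% L
}

jaccard_edges <- function(a, b) {
  ka <- paste(a[, 1], a[, 2])
  kb <- paste(b[, 1], b[, 2])
  length(intersect(ka, kb)) / length(union(ka, kb))
}
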