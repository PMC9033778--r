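#' First-order partial correlation controlling one covariate
#'
#' Correlation between `x` and `y` with the linear effect of a single
#' confounder removed:
#' `r_xy.z = (r_xy - r_xz r_yz) / sqrt((1 - r_xz^2)(1 - r_yz^2))`.
#' The two-sided p-value uses `t = r sqrt((n - 3) / (1 - r^2))` on
#' `n - 3` degrees of freedom.
#'
#' @param x,y,covariate Numeric vectors of equal length `n >= 4`.
#' @return List with `r_partial`, `p_value`, `n`.
#' @export
partial_correlation <- function(x, y, covariate) {
  n <- length(x)
  if (length(y) != n || length(covariate) != n) stop("unequal lengths")
  if (n < 4L) stop("need at least 4 observations (df = n - 3)")
  if (stats::sd(x) == 0 || stats::sd(y) == 0 || stats::sd(covariate) == 0) {
    stop("constant input vector")
  }
  rxy <- stats::cor(x, y)
  rxz <- stats::cor(x, covariate)
  ryz <- stats::cor(y, covariate)
  rp <- (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
  rp <- max(-1, min(1, rp))
  p <- .r_to_p(rp, n, df_loss = 3L)
  list(r_partial = rp, p_value = p, n = n)
}

# two-sided p for a correlation via the t transform
.r_to_p <- function(r, n, df_loss = 2L) {
  df <- n - df_loss
  tt <- r * sqrt(df / pmax(1 - r^2, .Machine$double.eps))
  2 * stats::pt(abs(tt), df, lower.tail = FALSE)
}

# Vectorized per-edge partial correlation of each column of V with y,
# controlling z. Constant columns get r = 0, p = 1 (never selected).
.edge_partial_cor <- function(V, y, z) {
  n <- length(y)
  sds <- sqrt(colSums(scale(V, scale = FALSE)^2))
  ok <- sds > 0
  ry <- rz <- numeric(ncol(V))
  if (any(ok)) {
    ry[ok] <- drop(stats::cor(V[, ok, drop = FALSE], y))
    rz[ok] <- drop(stats::cor(V[, ok, drop = FALSE], z))
  }
  ryz <- stats::cor(y, z)
  rp <- (ry - rz * ryz) / sqrt((1 - rz^2) * (1 - ryz^2))
  rp <- pmax(-1, pmin(1, rp))
  rp[!ok] <- 0
  p <- .r_to_p(rp, n, df_loss = 3L)
  p[!ok] <- 1
  list(r = rp, p = p)
}

#' Select behavior-correlated edges from a connectome stack
#'
#' Computes, for every edge, the partial correlation between its
#' connectivity values and the behavioral score controlling for age,
#' and splits edges with `p < p_threshold` (strict) into a positive and
#' a negative feature set by the sign of the partial correlation. Edges
#' with a partial correlation of exactly zero belong to neither set.
#'
#' @param stack A [build_connectome()] stack.
#' @param scores Behavioral score vector, one per subject (stack row).
#' @param ages Covariate vector (years), aligned with `scores`.
#' @param p_threshold Significance level in (0, 1); default 0.001.
#' @return Object of class `edge_selection`: list with `partial_r`,
#'   `p_value`, `positive_mask`, `negative_mask`, `p_threshold`,
#'   `n_subjects`.
#' @export
select_features <- function(stack, scores, ages, p_threshold = 0.001) {
  stopifnot(inherits(stack, "connectome_stack"))
  n <- nrow(stack$values)
  if (length(scores) != n || length(ages) != n) {
    stop("scores/ages not aligned with stack rows")
  }
  if (stats::sd(scores) == 0) stop("constant score vector")
  if (!is.numeric(p_threshold) || p_threshold <= 0 || p_threshold >= 1) {
    stop("p_threshold must lie in (0, 1)")
  }
  pc <- .edge_partial_cor(stack$values, scores, ages)
  sig <- pc$p < p_threshold
  structure(
    list(partial_r = pc$r,
         p_value = pc$p,
         positive_mask = sig & pc$r > 0,
         negative_mask = sig & pc$r < 0,
         p_threshold = p_threshold,
         n_subjects = n),
    class = "edge_selection"
  )
}

#' @export
print.edge_selection <- function(x, ...) {
  cat("Edge selection: p <", x$p_threshold, "on", x$n_subjects, "subjects\n")
  cat("  positive edges:", sum(x$positive_mask),
      "  negative edges:", sum(x$negative_mask),
      "  of", length(x$p_value), "\n")
  invisible(x)
}
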