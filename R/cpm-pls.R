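#' Single-component partial least squares regression
#'
#' Fits a one-latent-component PLS regression of a score on a matrix of
#' selected connectivity features. Predictors and response are
#' mean-centered; by default they are not variance-scaled (the selected
#' features share a common connectivity scale), which can be changed
#' with `scale = TRUE`. With a single component the fit has a closed
#' form: the weight vector is proportional to `X'y`, the latent score
#' is `t = Xw`, and the response loading is the least-squares
#' regression of `y` on `t`. Coefficients are returned on the original
#' predictor scale together with an intercept, so that
#' `prediction = intercept + X %*% coefficients`.
#'
#' @param X Numeric matrix, subjects x features (>= 3 rows, >= 1
#'   column).
#' @param y Score vector, non-constant.
#' @param scale Logical; divide each predictor column by its sample SD
#'   before fitting (coefficients are still reported on the original
#'   scale).
#' @return List with `coefficients`, `intercept`, `fitted`, `scale`.
#' @export
fit_pls1 <- function(X, y, scale = FALSE) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 3L) stop("need at least 3 subjects")
  if (ncol(X) < 1L) stop("need at least 1 feature")
  if (length(y) != n) stop("X and y misaligned")
  if (stats::sd(y) == 0) stop("constant response")
  xm <- colMeans(X)
  Xc <- sweep(X, 2L, xm)
  sds <- rep(1, ncol(X))
  if (scale) {
    sds <- sqrt(colSums(Xc^2) / (n - 1L))
    if (any(sds == 0)) stop("constant feature column cannot be scaled")
    Xc <- sweep(Xc, 2L, sds, `/`)
  }
  ym <- mean(y)
  yc <- y - ym
  w <- drop(crossprod(Xc, yc))
  wn <- sqrt(sum(w^2))
  if (wn == 0) stop("all features uncorrelated with the response (degenerate PLS direction)")
  w <- w / wn
  tt <- drop(Xc %*% w)
  b <- sum(tt * yc) / sum(tt^2)
  beta <- (w * b) / sds                 # back to the original scale
  intercept <- ym - sum(xm * beta)
  list(coefficients = beta,
       intercept = intercept,
       fitted = intercept + drop(X %*% beta),
       scale = scale)
}
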