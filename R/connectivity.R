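#' Column-wise z-scoring of an ROI time-series matrix
#'
#' Normalizes each ROI's BOLD time course by subtracting its mean and
#' dividing by its sample standard deviation (denominator `n - 1`).
#'
#' @param ts Numeric matrix, timepoints x ROIs.
#' @return Matrix of the same shape; every column has mean 0 and unit
#'   sample standard deviation.
#' @examples
#' z <- zscore_series(matrix(rnorm(300), 100, 3))
#' colMeans(z)  # ~ 0
#' @export
zscore_series <- function(ts) {
  ts <- as.matrix(ts)
  if (!is.numeric(ts)) stop("time series must be numeric")
  if (nrow(ts) < 3L) stop("need at least 3 timepoints")
  sds <- apply(ts, 2L, stats::sd)
  bad <- which(sds == 0 | !is.finite(sds))
  if (length(bad) > 0L) {
    stop("constant (zero-variance) ROI column(s): ",
         paste(bad, collapse = ", "))
  }
  scale(ts, center = TRUE, scale = sds)[, , drop = FALSE]
}

#' Binarize extreme events of a z-scored series
#'
#' Splits each normalized time course into an activation indicator `u`
#' (1 where the series reaches or exceeds the upper threshold) and a
#' deactivation indicator `l` (1 where it reaches or falls below the
#' lower threshold). With `method = "normal"` (default) the thresholds
#' are the standard normal quantiles `qnorm(q)` and `qnorm(1 - q)`;
#' with `method = "empirical"` per-column empirical quantiles of the
#' data are used instead (a sensitivity-analysis variant).
#'
#' Boundary convention: a value exactly equal to the upper threshold
#' counts as an activation extreme (and symmetrically for the lower
#' threshold).
#'
#' @param z Numeric matrix, timepoints x ROIs, already z-scored.
#' @param q Quantile in (0.5, 1); default 0.9.
#' @param method `"normal"` or `"empirical"` threshold rule.
#' @return Object of class `extreme_encoding`: list with binary
#'   matrices `u` and `l` (timepoints x ROIs), `q`, `threshold_high`,
#'   `threshold_low`, `method`.
#' @export
binarize_extremes <- function(z, q = 0.9, method = c("normal", "empirical")) {
  method <- match.arg(method)
  z <- as.matrix(z)
  if (!is.numeric(q) || length(q) != 1L || q <= 0.5 || q >= 1) {
    stop("q must lie in (0.5, 1)")
  }
  if (method == "normal") {
    hi <- stats::qnorm(q)
    lo <- stats::qnorm(1 - q)
    u <- (z >= hi) * 1L
    l <- (z <= lo) * 1L
  } else {
    hi <- apply(z, 2L, stats::quantile, probs = q, names = FALSE)
    lo <- apply(z, 2L, stats::quantile, probs = 1 - q, names = FALSE)
    u <- (sweep(z, 2L, hi, `>=`)) * 1L
    l <- (sweep(z, 2L, lo, `<=`)) * 1L
  }
  structure(
    list(u = u, l = l, q = q,
         threshold_high = hi, threshold_low = lo, method = method),
    class = "extreme_encoding"
  )
}

#' Accordance and discordance between two encoded ROIs
#'
#' Accumulates co-occurring extreme events between two regions:
#' accordance counts same-direction extremes
#' (`u_i.u_j + l_i.l_j`), discordance counts opposite-direction
#' extremes (`u_i.l_j + l_i.u_j`); both are normalized by the geometric
#' mean of the per-region extreme-event counts
#' `sigma_i = sqrt(u_i.u_i + l_i.l_i)`.
#'
#' @param u_i,l_i Binary activation/deactivation indicators for ROI i.
#' @param u_j,l_j Indicators for ROI j.
#' @return Named numeric vector `c(accordance = a, discordance = d)`,
#'   each in \[0, 1\] with `a + d <= 1`.
#' @export
pair_accordance_discordance <- function(u_i, l_i, u_j, l_j) {
  s_i <- sqrt(sum(u_i * u_i) + sum(l_i * l_i))
  s_j <- sqrt(sum(u_j * u_j) + sum(l_j * l_j))
  if (s_i == 0) stop("ROI i has no extreme events (sigma = 0)")
  if (s_j == 0) stop("ROI j has no extreme events (sigma = 0)")
  a <- (sum(u_i * u_j) + sum(l_i * l_j)) / (s_i * s_j)
  d <- (sum(u_i * l_j) + sum(l_i * u_j)) / (s_i * s_j)
  c(accordance = a, discordance = d)
}

#' Edge index for an upper-triangular vectorization
#'
#' Row-major upper triangle, 0-based, i < j: (0,1), (0,2), ...,
#' (0,n-1), (1,2), ...
#'
#' @param n_rois Number of nodes.
#' @return Integer matrix with columns `i`, `j` and
#'   `n_rois * (n_rois - 1) / 2` rows.
#' @export
edge_index <- function(n_rois) {
  n_rois <- as.integer(n_rois)
  if (is.na(n_rois) || n_rois < 2L) stop("need at least 2 ROIs")
  i <- rep.int(seq_len(n_rois - 1L) - 1L, times = (n_rois - 1L):1L)
  j <- unlist(lapply(seq_len(n_rois - 1L), function(k) k:(n_rois - 1L)),
              use.names = FALSE)
  cbind(i = i, j = j)
}

# Extract the row-major upper triangle of a symmetric matrix as a vector
# ordered like edge_index(nrow(m)).
.upper_vec <- function(m, idx) {
  m[cbind(idx[, 1L] + 1L, idx[, 2L] + 1L)]
}

#' Build a subjects-by-edges connectome stack
#'
#' Computes, for every subject, one connectivity value per node pair and
#' stacks them into a subjects x edges matrix. Three profiles are
#' supported: `"pearson"` (Pearson correlation of the z-scored series),
#' `"accordance"` and `"discordance"` (extreme-event measures at
#' quantile `q`).
#'
#' @param series List of per-subject numeric matrices (timepoints x
#'   ROIs), all with the same ROI count and ordering.
#' @param profile One of `"pearson"`, `"accordance"`, `"discordance"`.
#' @param q Extreme-event quantile (ignored for the pearson profile).
#' @param method Threshold rule passed to [binarize_extremes()].
#' @return Object of class `connectome_stack`: list with `values`
#'   (subjects x edges matrix), `profile`, `q` (NA for pearson),
#'   `n_rois`, `edge_index` (0-based, i < j, row-major), `method`,
#'   `subject_ids`.
#' @examples
#' ser <- replicate(3, matrix(rnorm(600), 100, 6), simplify = FALSE)
#' stk <- build_connectome(ser, "discordance", q = 0.9)
#' dim(stk$values)  # 3 x 15
#' @export
build_connectome <- function(series,
                             profile = c("pearson", "accordance", "discordance"),
                             q = 0.9,
                             method = c("normal", "empirical")) {
  profile <- match.arg(profile)
  method <- match.arg(method)
  if (is.array(series) && length(dim(series)) == 3L) {
    # subjects x rois x timepoints array -> list of T x R matrices
    series <- lapply(seq_len(dim(series)[1L]),
                     function(s) t(series[s, , ]))
  }
  if (!is.list(series) || length(series) == 0L) {
    stop("series must be a non-empty list of timepoints x ROIs matrices")
  }
  n_rois <- ncol(series[[1L]])
  rois_per_subj <- vapply(series, ncol, integer(1L))
  if (any(rois_per_subj != n_rois)) {
    stop("ragged ROI counts across subjects: ",
         paste(which(rois_per_subj != n_rois), collapse = ", "))
  }
  idx <- edge_index(n_rois)
  ids <- names(series)
  if (is.null(ids)) ids <- paste0("sub", seq_along(series))

  rows <- lapply(seq_along(series), function(s) {
    z <- tryCatch(zscore_series(series[[s]]),
                  error = function(e) {
                    stop("subject ", ids[s], ": ", conditionMessage(e),
                         call. = FALSE)
                  })
    if (profile == "pearson") {
      .upper_vec(stats::cor(z), idx)
    } else {
      enc <- binarize_extremes(z, q = q, method = method)
      sig <- sqrt(colSums(enc$u) + colSums(enc$l))
      if (any(sig == 0)) {
        stop("subject ", ids[s], ": ROI(s) with no extreme events: ",
             paste(which(sig == 0), collapse = ", "), call. = FALSE)
      }
      uu <- crossprod(enc$u)            # u_i . u_j
      ll <- crossprod(enc$l)
      denom <- tcrossprod(sig)
      if (profile == "accordance") {
        .upper_vec((uu + ll) / denom, idx)
      } else {
        ul <- crossprod(enc$u, enc$l)   # u_i . l_j
        .upper_vec((ul + t(ul)) / denom, idx)
      }
    }
  })
  values <- do.call(rbind, rows)
  rownames(values) <- ids
  structure(
    list(values = values,
         profile = profile,
         q = if (profile == "pearson") NA_real_ else q,
         n_rois = n_rois,
         edge_index = idx,
         method = if (profile == "pearson") NA_character_ else method,
         subject_ids = ids),
    class = "connectome_stack"
  )
}

#' @export
print.connectome_stack <- function(x, ...) {
  cat("Connectome stack (", x$profile, ")\n", sep = "")
  cat("  subjects:", nrow(x$values), "  ROIs:", x$n_rois,
      "  edges:", ncol(x$values), "\n")
  if (!is.na(x$q)) cat("  extreme-event quantile q =", x$q,
                       "(", x$method, "thresholds )\n")
  invisible(x)
}
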