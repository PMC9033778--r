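#' Leave-one-out cross-validation of the CPM pipeline
#'
#' For each held-out subject, edge selection AND the PLS fit are redone
#' on the remaining `n - 1` subjects only, and the held-out subject's
#' score is predicted from their connectivity on that fold's edges. If
#' a fold selects no edge at the threshold, the held-out prediction
#' falls back to the training mean of the score and the event is
#' reported (loudly) in the result; this keeps the cross-validation
#' defined at strict thresholds on small cohorts.
#'
#' @inheritParams cpm_train
#' @return Object of class `cpm_cv`: list with `predicted`, `observed`,
#'   `fold_edges` (list of 0-based edge matrices, one per fold),
#'   `fold_masks` (logical matrix, folds x edges), `empty_folds`
#'   (indices of mean-imputed folds), `eval` (a [evaluate_predictions()]
#'   result), plus the pipeline parameters.
#' @export
cpm_loocv <- function(stack, scores, ages,
                      p_threshold = 0.001,
                      sign = c("positive", "negative"),
                      scale = FALSE) {
  sign <- match.arg(sign)
  stopifnot(inherits(stack, "connectome_stack"))
  n <- nrow(stack$values)
  if (length(scores) != n || length(ages) != n) {
    stop("scores/ages not aligned with stack rows")
  }
  V <- stack$values
  predicted <- numeric(n)
  masks <- matrix(FALSE, n, ncol(V))
  empty <- integer(0)
  for (i in seq_len(n)) {
    Vtr <- V[-i, , drop = FALSE]
    ytr <- scores[-i]
    pc <- .edge_partial_cor(Vtr, ytr, ages[-i])
    sig <- pc$p < p_threshold
    mask <- if (sign == "positive") sig & pc$r > 0 else sig & pc$r < 0
    masks[i, ] <- mask
    if (!any(mask)) {
      predicted[i] <- mean(ytr)
      empty <- c(empty, i)
      next
    }
    fit <- fit_pls1(Vtr[, mask, drop = FALSE], ytr, scale = scale)
    predicted[i] <- fit$intercept +
      sum(V[i, mask] * fit$coefficients)
  }
  if (length(empty) > 0L) {
    warning(length(empty), " fold(s) selected zero edges at p < ",
            p_threshold, "; held-out prediction fell back to the ",
            "training mean (folds: ",
            paste(utils::head(empty, 10L), collapse = ", "),
            if (length(empty) > 10L) ", ..." else "", ")")
  }
  structure(
    list(predicted = predicted,
         observed = scores,
         fold_edges = lapply(seq_len(n), function(i) {
           stack$edge_index[masks[i, ], , drop = FALSE]
         }),
         fold_masks = masks,
         edge_index = stack$edge_index,
         empty_folds = empty,
         eval = evaluate_predictions(predicted, scores),
         profile = stack$profile,
         sign = sign,
         q = stack$q,
         p_threshold = p_threshold),
    class = "cpm_cv"
  )
}

#' @export
print.cpm_cv <- function(x, ...) {
  cat("Leave-one-out CPM evaluation (", x$profile, " ", x$sign,
      " network)\n", sep = "")
  cat("  folds:", length(x$predicted),
      "  selection p <", x$p_threshold, "\n")
  cat("  r(predicted, observed) =", format(x$eval$r, digits = 4),
      "  predicted R^2 =", format(x$eval$r_squared, digits = 4), "\n")
  if (length(x$empty_folds) > 0L) {
    cat("  NOTE:", length(x$empty_folds),
        "fold(s) used mean imputation (no edges selected)\n")
  }
  invisible(x)
}

#' @export
plot.cpm_cv <- function(x, ...) {
  plot(x$observed, x$predicted,
       xlab = "Observed score", ylab = "Predicted score (LOOCV)",
       main = sprintf("%s %s network: r = %.2f, R2 = %.2f",
                      x$profile, x$sign, x$eval$r, x$eval$r_squared),
       ...)
  graphics::abline(stats::lm(x$predicted ~ x$observed), lty = 2)
  invisible(x)
}

#' Prediction-accuracy summary: Pearson r and predicted R-squared
#'
#' Predicted R-squared is `1 - SSE / SST`, where SSE is the sum of
#' squared prediction errors and SST the total sum of squares of the
#' observed scores about their own mean. Unlike an in-sample R-squared
#' it can be negative: a model predicting worse than the observed mean.
#' When the predictions are constant, r is undefined and reported as
#' NA; R-squared is still computed.
#'
#' @param predicted,observed Numeric vectors of equal length >= 3.
#' @return Object of class `prediction_eval`: list with `predicted`,
#'   `observed`, `r`, `r_squared`, `sse`, `sst`.
#' @export
evaluate_predictions <- function(predicted, observed) {
  n <- length(observed)
  if (length(predicted) != n) stop("unequal lengths")
  if (n < 3L) stop("need at least 3 subjects")
  sse <- sum((observed - predicted)^2)
  sst <- sum((observed - mean(observed))^2)
  r <- if (stats::sd(predicted) == 0 || stats::sd(observed) == 0) {
    NA_real_
  } else {
    stats::cor(predicted, observed)
  }
  structure(
    list(predicted = predicted, observed = observed,
         r = r, r_squared = 1 - sse / sst, sse = sse, sst = sst),
    class = "prediction_eval"
  )
}

#' @export
print.prediction_eval <- function(x, ...) {
  cat("Prediction evaluation on", length(x$observed), "subjects\n")
  cat("  r =", format(x$r, digits = 4),
      "  R^2 =", format(x$r_squared, digits = 4),
      "  (SSE =", format(x$sse, digits = 4),
      ", SST =", format(x$sst, digits = 4), ")\n")
  invisible(x)
}

#' Consensus edges across cross-validation folds
#'
#' Returns the edges selected in at least `retain_fraction` of folds,
#' on the exact count: an edge is kept iff its selection count is
#' `>= ceiling(retain_fraction * n_folds)`.
#'
#' @param cv A [cpm_loocv()] result (or a logical folds x edges matrix).
#' @param retain_fraction Fraction in (0, 1]; the robustness thresholds
#'   commonly reported are 0.90, 0.95 and 1.
#' @return Integer matrix of consensus edges (0-based `i`, `j`
#'   columns), with attribute `counts` (per retained edge).
#' @export
consensus_edges <- function(cv, retain_fraction = 0.95) {
  if (inherits(cv, "cpm_cv")) {
    masks <- cv$fold_masks
    edge_idx <- cv$edge_index
  } else {
    masks <- cv
    n_rois <- (1 + sqrt(1 + 8 * ncol(masks))) / 2
    edge_idx <- edge_index(round(n_rois))
  }
  if (is.null(dim(masks)) || nrow(masks) == 0L) stop("empty fold list")
  if (!is.numeric(retain_fraction) || retain_fraction <= 0 ||
      retain_fraction > 1) {
    stop("retain_fraction must lie in (0, 1]")
  }
  counts <- colSums(masks)
  need <- ceiling(retain_fraction * nrow(masks))
  keep <- counts >= need
  out <- edge_idx[keep, , drop = FALSE]
  attr(out, "counts") <- counts[keep]
  out
}

#' Stability sweep over the binarization and selection thresholds
#'
#' Repeats the LOOCV pipeline over a grid of extreme-event quantiles
#' `q` and selection thresholds `p` for one or more candidate models
#' (profile x sign), recording the cross-validated Pearson r in every
#' cell. The reference analysis uses q from 0.8 to 0.9 in steps of 0.01
#' and p from 0.001 to 0.01 in steps of 0.001 (110 cells).
#'
#' @param series List of per-subject timepoints x ROIs matrices.
#' @param scores,ages Phenotype vectors aligned with `series`.
#' @param q_grid,p_grid Non-empty numeric grids.
#' @param models List of `c(profile, sign)` pairs, e.g.
#'   `list(c("discordance", "positive"), c("accordance", "negative"))`.
#' @return Object of class `cpm_sweep`: list with `r` (array cells x
#'   models of LOOCV r), `q_grid`, `p_grid`, `models` (named
#'   "profile_sign").
#' @seealso [compare_sweep_models()] for the paired comparison.
#' @export
parameter_sweep <- function(series, scores, ages,
                            q_grid = seq(0.80, 0.90, by = 0.01),
                            p_grid = seq(0.001, 0.010, by = 0.001),
                            models = list(c("discordance", "positive"))) {
  if (length(q_grid) == 0L || length(p_grid) == 0L) stop("empty grid")
  model_names <- vapply(models, paste, character(1L), collapse = "_")
  r <- array(NA_real_,
             dim = c(length(q_grid), length(p_grid), length(models)),
             dimnames = list(paste0("q", q_grid), paste0("p", p_grid),
                             model_names))
  profiles <- unique(vapply(models, `[`, character(1L), 1L))
  for (qi in seq_along(q_grid)) {
    stacks <- lapply(profiles, function(pr) {
      build_connectome(series, profile = pr, q = q_grid[qi])
    })
    names(stacks) <- profiles
    for (pi in seq_along(p_grid)) {
      for (mi in seq_along(models)) {
        cvr <- suppressWarnings(
          cpm_loocv(stacks[[models[[mi]][1L]]], scores, ages,
                    p_threshold = p_grid[pi],
                    sign = models[[mi]][2L])
        )
        r[qi, pi, mi] <- cvr$eval$r
      }
    }
  }
  structure(
    list(r = r, q_grid = q_grid, p_grid = p_grid, models = model_names),
    class = "cpm_sweep"
  )
}

#' Paired comparison of two models across sweep cells
#'
#' Two-sided paired t-test of the LOOCV r values of two models over the
#' same (q, p) grid cells; degrees of freedom = cells - 1.
#'
#' @param sweep A [parameter_sweep()] result.
#' @param model_a,model_b Model names as in `sweep$models`.
#' @return List with `t`, `df`, `p_value`, `mean_diff`, `n_cells`.
#' @export
compare_sweep_models <- function(sweep, model_a, model_b) {
  stopifnot(inherits(sweep, "cpm_sweep"))
  a <- as.vector(sweep$r[, , model_a])
  b <- as.vector(sweep$r[, , model_b])
  d <- a - b
  d <- d[is.finite(d)]
  n <- length(d)
  if (n < 2L) stop("need at least 2 grid cells for a paired t-test")
  if (stats::sd(d) == 0) {
    stop("zero variance of paired differences; t undefined")
  }
  ht <- stats::t.test(d)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value, mean_diff = mean(d), n_cells = n)
}
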