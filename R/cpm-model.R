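#' Train a fixed-parameter connectome-based predictive model
#'
#' Runs the full CPM training stage once on a whole cohort: per-edge
#' partial correlation of connectivity with the score controlling age,
#' selection of the significant edges of the requested sign, and a
#' single-component PLS regression of the score on those edges. The
#' returned model freezes its hyperparameters (connectivity profile,
#' extreme-event quantile `q`, selection threshold, sign) so it can be
#' applied unchanged to independent cohorts with [predict.cpm_model()].
#'
#' @param stack A [build_connectome()] stack for the training cohort.
#' @param scores Behavioral score vector (one per stack row).
#' @param ages Age covariate used during edge selection.
#' @param p_threshold Selection level, strict `p <` comparison;
#'   default 0.001.
#' @param sign `"positive"` or `"negative"`: keep edges whose partial
#'   correlation with the score has this sign.
#' @param scale Passed to [fit_pls1()].
#' @return Object of class `cpm_model`: list with `edges` (0-based
#'   node-pair matrix), `coefficients`, `intercept`, `profile`, `sign`,
#'   `q`, `method`, `p_threshold`, `n_rois`, `training_n`, `scale`,
#'   `selection` (the full [select_features()] result).
#' @seealso [cpm_loocv()] for cross-validated evaluation,
#'   [write_cpm_model()] for serialization.
#' @export
cpm_train <- function(stack, scores, ages,
                      p_threshold = 0.001,
                      sign = c("positive", "negative"),
                      scale = FALSE) {
  sign <- match.arg(sign)
  sel <- select_features(stack, scores, ages, p_threshold)
  mask <- if (sign == "positive") sel$positive_mask else sel$negative_mask
  if (!any(mask)) {
    stop("no edges selected at p < ", p_threshold,
         " with ", sign, " partial correlation; cannot build a model")
  }
  fit <- fit_pls1(stack$values[, mask, drop = FALSE], scores, scale = scale)
  structure(
    list(edges = stack$edge_index[mask, , drop = FALSE],
         coefficients = fit$coefficients,
         intercept = fit$intercept,
         profile = stack$profile,
         sign = sign,
         q = stack$q,
         method = stack$method,
         p_threshold = p_threshold,
         n_rois = stack$n_rois,
         training_n = nrow(stack$values),
         scale = scale,
         selection = sel),
    class = "cpm_model"
  )
}

#' Apply a fixed CPM model to a new connectome stack
#'
#' Prediction is `intercept + sum(coefficient * FC)` over the model's
#' edges only. The new stack must match the model's parcellation size,
#' connectivity profile and extreme-event quantile; mismatches are hard
#' errors because the coefficients are not transferable across them.
#'
#' @param object A [cpm_train()] model.
#' @param newdata A `connectome_stack` from an independent cohort.
#' @param ... Unused.
#' @return Numeric vector of predicted scores, one per subject.
#' @export
predict.cpm_model <- function(object, newdata, ...) {
  stopifnot(inherits(newdata, "connectome_stack"))
  if (newdata$n_rois != object$n_rois) {
    stop("parcellation mismatch: model has ", object$n_rois,
         " ROIs, new stack has ", newdata$n_rois)
  }
  if (newdata$profile != object$profile) {
    stop("profile mismatch: model is ", object$profile,
         ", new stack is ", newdata$profile)
  }
  if (!identical(is.na(newdata$q), is.na(object$q)) ||
      (!is.na(object$q) && newdata$q != object$q)) {
    stop("extreme-event quantile mismatch: model q = ", object$q,
         ", new stack q = ", newdata$q)
  }
  cols <- match(
    paste(object$edges[, 1L], object$edges[, 2L]),
    paste(newdata$edge_index[, 1L], newdata$edge_index[, 2L])
  )
  X <- newdata$values[, cols, drop = FALSE]
  object$intercept + drop(X %*% object$coefficients)
}

#' @export
coef.cpm_model <- function(object, ...) {
  stats::setNames(
    object$coefficients,
    paste0("(", object$edges[, 1L], ",", object$edges[, 2L], ")")
  )
}

#' @export
print.cpm_model <- function(x, ...) {
  cat("Connectome-based predictive model (", x$profile, " ", x$sign,
      " network)\n", sep = "")
  cat("  ", nrow(x$edges), " edges over ", x$n_rois, " ROIs; trained on ",
      x$training_n, " subjects\n", sep = "")
  cat("  selection p < ", x$p_threshold,
      if (!is.na(x$q)) paste0("; q = ", x$q), "\n", sep = "")
  invisible(x)
}

#' @export
summary.cpm_model <- function(object, ...) {
  print(object)
  cat("  intercept:", format(object$intercept), "\n")
  cat("  coefficient range: [",
      format(min(object$coefficients)), ", ",
      format(max(object$coefficients)), "]\n", sep = "")
  invisible(object)
}

#' Serialize a CPM model to JSON
#'
#' Writes all model fields needed to reproduce predictions bit-for-bit
#' (edges as 0-based `[i, j]` pairs with `i < j`, coefficients at full
#' float precision, intercept, and the frozen hyperparameters).
#'
#' @param model A `cpm_model`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cpm_model <- function(model, path) {
  stopifnot(inherits(model, "cpm_model"))
  obj <- list(
    profile = model$profile,
    sign = model$sign,
    q = model$q,
    method = model$method,
    p_threshold = model$p_threshold,
    n_rois = model$n_rois,
    edges = unname(apply(model$edges, 1L, function(e) as.integer(e),
                         simplify = FALSE)),
    coefficients = as.numeric(model$coefficients),
    intercept = model$intercept,
    training_n = model$training_n,
    scale = model$scale
  )
  # digits = I(17): doubles survive the decimal round-trip bit-for-bit
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' Read a CPM model written by [write_cpm_model()]
#'
#' @param path JSON file path.
#' @return A `cpm_model` (without the training-time `selection` field).
#' @export
read_cpm_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  e <- obj$edges
  if (is.list(e)) e <- do.call(rbind, e)
  if (is.null(dim(e))) e <- matrix(e, ncol = 2L, byrow = TRUE)
  edges <- matrix(as.integer(e), ncol = 2L,
                  dimnames = list(NULL, c("i", "j")))
  structure(
    list(edges = edges,
         coefficients = as.numeric(obj$coefficients),
         intercept = as.numeric(obj$intercept),
         profile = obj$profile,
         sign = obj$sign,
         q = if (is.null(obj$q)) NA_real_ else as.numeric(obj$q),
         method = if (is.null(obj$method)) NA_character_ else obj$method,
         p_threshold = as.numeric(obj$p_threshold),
         n_rois = as.integer(obj$n_rois),
         training_n = as.integer(obj$training_n),
         scale = isTRUE(obj$scale),
         selection = NULL),
    class = "cpm_model"
  )
}
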