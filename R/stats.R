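#' Permutation test of a cross-validated prediction correlation
#'
#' Shuffles the behavioral scores and reruns the ENTIRE leave-one-out
#' pipeline — edge selection inside every fold included — for each
#' permutation, building a null distribution of cross-validated
#' Pearson r values. The p-value is the fraction of null r values
#' greater than or equal to the true r; because this estimator can be
#' exactly zero, the add-one estimator `(k + 1) / (n_perm + 1)` is also
#' reported as `p_add_one`.
#'
#' @inheritParams cpm_train
#' @param n_perm Number of permutations (>= 1). The reference analysis
#'   uses 10,000; calibration experiments use far fewer.
#' @param seed Integer seed controlling the permutation stream.
#' @return Object of class `cpm_perm`: list with `r_true`, `null_rs`,
#'   `n_perm`, `p_value`, `p_add_one`, `seed`.
#' @export
permutation_test <- function(stack, scores, ages,
                             p_threshold = 0.001,
                             sign = c("positive", "negative"),
                             n_perm = 1000, seed = 1) {
  sign <- match.arg(sign)
  if (n_perm < 1L) stop("n_perm must be >= 1")
  if (stats::sd(scores) == 0) stop("constant score vector")
  true_cv <- suppressWarnings(
    cpm_loocv(stack, scores, ages, p_threshold = p_threshold, sign = sign)
  )
  r_true <- true_cv$eval$r
  null_rs <- numeric(n_perm)
  old_seed <- .save_rng()
  on.exit(.restore_rng(old_seed), add = TRUE)
  set.seed(seed)
  for (b in seq_len(n_perm)) {
    y_perm <- sample(scores)
    cv <- suppressWarnings(
      cpm_loocv(stack, y_perm, ages, p_threshold = p_threshold, sign = sign)
    )
    null_rs[b] <- cv$eval$r
  }
  null_ok <- null_rs
  null_ok[is.na(null_ok)] <- -Inf     # constant-prediction permutations
  k <- sum(null_ok >= r_true)
  structure(
    list(r_true = r_true, null_rs = null_rs, n_perm = n_perm,
         p_value = k / n_perm, p_add_one = (k + 1) / (n_perm + 1),
         seed = seed),
    class = "cpm_perm"
  )
}

#' @export
print.cpm_perm <- function(x, ...) {
  cat("Permutation test (", x$n_perm, " permutations, seed ", x$seed,
      ")\n", sep = "")
  cat("  true LOOCV r =", format(x$r_true, digits = 4),
      "  p =", format(x$p_value, digits = 4),
      " (add-one:", format(x$p_add_one, digits = 4), ")\n")
  invisible(x)
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Steiger's z test for two dependent overlapping correlations
#'
#' Compares `r12` and `r13` — two correlations sharing variable 1 —
#' given the correlation `r23` between the non-shared variables (the
#' typical use here: predicted scores from two candidate models, each
#' correlated with the same observed scores). Uses the pooled-r
#' variant: both correlations are Fisher-transformed, the pooled
#' `rbar = (r12 + r13) / 2` enters the covariance term
#' `s = (r23 (1 - 2 rbar^2) - rbar^2 (1 - 2 rbar^2 - r23^2) / 2) /
#' (1 - rbar^2)^2`, and
#' `z = (z12 - z13) sqrt((n - 3) / (2 (1 - s)))` is referred to the
#' standard normal.
#'
#' @param r12,r13 The two dependent correlations (|r| < 1).
#' @param r23 Correlation between the two non-shared variables.
#' @param n Sample size (>= 4).
#' @return List with `z` and two-sided `p_value`.
#' @export
steiger_z <- function(r12, r13, r23, n) {
  if (any(abs(c(r12, r13, r23)) >= 1)) stop("correlations must satisfy |r| < 1")
  if (n < 4L) stop("need n >= 4")
  z12 <- atanh(r12)
  z13 <- atanh(r13)
  rbar <- (r12 + r13) / 2
  s <- (r23 * (1 - 2 * rbar^2) - 0.5 * rbar^2 * (1 - 2 * rbar^2 - r23^2)) /
    (1 - rbar^2)^2
  z <- (z12 - z13) * sqrt((n - 3) / (2 * (1 - s)))
  list(z = z, p_value = 2 * stats::pnorm(abs(z), lower.tail = FALSE))
}

#' Chi-square test on a 2x2 contingency table
#'
#' Pearson chi-square with 1 degree of freedom; Yates continuity
#' correction is applied by default (it reproduces the printed
#' demographic sex comparisons of the reference cohorts).
#'
#' @param counts 2x2 matrix of nonnegative integer counts.
#' @param continuity_correction Apply the Yates correction (default
#'   TRUE).
#' @return List with `chi2`, `p_value`, `df`.
#' @export
chi_square_2x2 <- function(counts, continuity_correction = TRUE) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(2L, 2L))) stop("counts must be a 2x2 table")
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be nonnegative integers")
  }
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    stop("zero row/column margin")
  }
  ht <- suppressWarnings(
    stats::chisq.test(counts, correct = continuity_correction)
  )
  list(chi2 = unname(ht$statistic), p_value = ht$p.value,
       df = unname(ht$parameter))
}

#' Two-sample t-test from summary statistics
#'
#' Two-sided test computed from group means, SDs and sizes — the form
#' needed to check published demographic tables. `variant = "pooled"`
#' is the classic Student test (equal variances assumed);
#' `variant = "welch"` uses the Welch–Satterthwaite approximation.
#'
#' @param m1,s1,n1 Mean, SD, size of group 1 (`n1 >= 2`, `s1 > 0`).
#' @param m2,s2,n2 Same for group 2.
#' @param variant `"pooled"` or `"welch"`.
#' @return List with `t`, `df`, `p_value`.
#' @export
t_test_from_summary <- function(m1, s1, n1, m2, s2, n2,
                                variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  if (n1 < 2L || n2 < 2L) stop("each group needs n >= 2")
  if (s1 <= 0 || s2 <= 0) stop("SDs must be positive")
  if (variant == "pooled") {
    sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    v1 <- s1^2 / n1
    v2 <- s2^2 / n2
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  }
  tt <- (m1 - m2) / se
  list(t = tt, df = df,
       p_value = 2 * stats::pt(abs(tt), df, lower.tail = FALSE))
}

#' Spearman rank correlation with t-approximation p-value
#'
#' Pearson correlation of mid-ranks (average ranks on ties); the
#' two-sided p-value uses the t approximation
#' `t = rho sqrt((n - 2) / (1 - rho^2))` on `n - 2` df.
#'
#' @param x,y Numeric vectors of equal length >= 4.
#' @return List with `rho` and `p_value`.
#' @export
spearman_corr <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop("unequal lengths")
  if (n < 4L) stop("need at least 4 observations")
  rx <- rank(x)
  ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) stop("constant vector")
  rho <- stats::cor(rx, ry)
  p <- if (abs(rho) >= 1) 0 else .r_to_p(rho, n, df_loss = 2L)
  list(rho = rho, p_value = p)
}

#' Specificity screen of predicted scores against extraneous variables
#'
#' Checks that a model's predicted scores track the intended behavioral
#' score and not demographic or nuisance variables: Pearson r and p of
#' the predictions against age, mean framewise displacement, education
#' and cognition (MoCA), each on pairwise-complete observations (the
#' number dropped is reported per variable), plus a two-sample t-test
#' of the predictions between the sexes.
#'
#' @param predicted Numeric vector of predicted scores.
#' @param phenotypes Data frame aligned with `predicted`; recognised
#'   columns among `age`, `mean_fd`, `education`, `moca` are screened,
#'   and `sex` (levels "M"/"F") triggers the sex comparison.
#' @return Object of class `specificity_screen`: data frame
#'   `correlations` (variable, n, r, p_value, n_missing) and list
#'   `sex_test` (t, df, p_value) or NULL.
#' @export
specificity_screen <- function(predicted, phenotypes) {
  n <- length(predicted)
  if (nrow(phenotypes) != n) stop("phenotypes not aligned with predictions")
  vars <- intersect(c("age", "mean_fd", "education", "moca"),
                    names(phenotypes))
  rows <- lapply(vars, function(v) {
    xv <- phenotypes[[v]]
    ok <- is.finite(predicted) & !is.na(xv)
    n_ok <- sum(ok)
    if (n_ok < 4L || stats::sd(xv[ok]) == 0 || stats::sd(predicted[ok]) == 0) {
      return(data.frame(variable = v, n = n_ok, r = NA_real_,
                        p_value = NA_real_, n_missing = n - n_ok))
    }
    r <- stats::cor(predicted[ok], xv[ok])
    data.frame(variable = v, n = n_ok, r = r,
               p_value = .r_to_p(r, n_ok, df_loss = 2L),
               n_missing = n - n_ok)
  })
  correlations <- do.call(rbind, rows)
  sex_test <- NULL
  if ("sex" %in% names(phenotypes)) {
    sx <- phenotypes$sex
    ok <- !is.na(sx) & is.finite(predicted)
    if (length(unique(sx[ok])) == 2L && all(table(sx[ok]) >= 2L)) {
      ht <- stats::t.test(predicted[ok] ~ sx[ok], var.equal = TRUE)
      sex_test <- list(t = unname(ht$statistic),
                       df = unname(ht$parameter),
                       p_value = ht$p.value)
    }
  }
  structure(list(correlations = correlations, sex_test = sex_test),
            class = "specificity_screen")
}

#' @export
print.specificity_screen <- function(x, ...) {
  cat("Specificity screen of predicted scores\n")
  print(x$correlations, row.names = FALSE)
  if (!is.null(x$sex_test)) {
    cat("  sex difference: t =", format(x$sex_test$t, digits = 4),
        ", p =", format(x$sex_test$p_value, digits = 4), "\n")
  }
  invisible(x)
}
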