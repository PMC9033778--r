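test_that("permutation test is seeded, bounded and consistent with its formula", {
  co <- small_planted_cohort(seed = 11, n_subjects = 25, n_rois = 10,
                             n_timepoints = 60, n_edges = 4)
  stk <- build_connectome(co$series, "discordance", q = 0.9)
  pt1 <- permutation_test(stk, co$phenotypes$score, co$phenotypes$age,
                          p_threshold = 0.05, n_perm = 25, seed = 7)
  pt2 <- permutation_test(stk, co$phenotypes$score, co$phenotypes$age,
                          p_threshold = 0.05, n_perm = 25, seed = 7)
  expect_identical(pt1$null_rs, pt2$null_rs)

  k <- sum(pt1$null_rs >= pt1$r_true, na.rm = TRUE)
  expect_equal(pt1$p_value, k / 25)
  expect_equal(pt1$p_add_one, (k + 1) / 26)
  # strong planted signal: true r above every permuted r -> p hits 0
  expect_equal(pt1$p_value, 0)
  expect_gt(pt1$p_add_one, 0)

  expect_error(permutation_test(stk, co$phenotypes$score,
                                co$phenotypes$age, n_perm = 0), "n_perm")
})

test_that("Steiger's z is antisymmetric, null at equality and grows with n", {
  s0 <- steiger_z(0.4, 0.4, 0.2, 50)
  expect_equal(s0$z, 0)
  expect_equal(s0$p_value, 1)

  sa <- steiger_z(0.6, 0.3, 0.4, 80)
  sb <- steiger_z(0.3, 0.6, 0.4, 80)
  expect_equal(sa$z, -sb$z)
  expect_equal(sa$p_value, sb$p_value)

  z_small <- abs(steiger_z(0.6, 0.3, 0.4, 20)$z)
  z_big <- abs(steiger_z(0.6, 0.3, 0.4, 200)$z)
  expect_gt(z_big, z_small)

  expect_error(steiger_z(1, 0.3, 0.4, 50), "\\|r\\|")
  expect_error(steiger_z(0.5, 0.3, 0.4, 3), "n >= 4")
})

test_that("2x2 chi-square honours the Yates flag and the Pearson formula", {
  # identical rows: no association
  eq <- chi_square_2x2(matrix(c(10, 10, 20, 20), 2), FALSE)
  expect_equal(eq$chi2, 0)
  expect_equal(eq$p_value, 1)

  # without correction, matches the classic algebraic formula
  set.seed(15)
  for (rep in 1:10) {
    m <- matrix(rpois(4, 20) + 1, 2)
    a <- m[1, 1]; b <- m[1, 2]; c <- m[2, 1]; d <- m[2, 2]
    n <- sum(m)
    chi_formula <- n * (a * d - b * c)^2 /
      ((a + b) * (c + d) * (a + c) * (b + d))
    expect_equal(chi_square_2x2(m, FALSE)$chi2, chi_formula,
                 tolerance = 1e-12)
  }
  expect_error(chi_square_2x2(matrix(c(0, 0, 5, 5), 2)), "margin")
  expect_error(chi_square_2x2(matrix(c(1.5, 2, 3, 4), 2)), "integer")
})

test_that("summary-statistic t-tests agree with raw-data t.test", {
  set.seed(16)
  x <- rnorm(14, 1, 2); y <- rnorm(19, 0, 3)
  for (variant in c("pooled", "welch")) {
    mine <- t_test_from_summary(mean(x), sd(x), 14, mean(y), sd(y), 19,
                                variant)
    ref <- t.test(x, y, var.equal = (variant == "pooled"))
    expect_equal(mine$t, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(mine$df, unname(ref$parameter), tolerance = 1e-12)
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-12)
  }
  same <- t_test_from_summary(5, 1, 10, 5, 2, 12)
  expect_equal(same$t, 0)
  expect_equal(same$p_value, 1)
  expect_error(t_test_from_summary(1, 0, 10, 2, 1, 10), "positive")
})

test_that("Spearman correlation handles monotone data and ties like the mid-rank oracle", {
  x <- c(1, 3, 5, 7, 9)
  expect_equal(spearman_corr(x, exp(x))$rho, 1)
  expect_equal(spearman_corr(x, -x^3)$rho, -1)

  set.seed(17)
  xt <- sample(1:4, 30, replace = TRUE)   # heavy ties
  yt <- xt + sample(0:2, 30, replace = TRUE)
  mine <- spearman_corr(xt, yt)
  ref <- suppressWarnings(cor.test(xt, yt, method = "spearman",
                                   exact = FALSE))
  expect_equal(mine$rho, unname(ref$estimate), tolerance = 1e-12)
  expect_equal(mine$p_value, ref$p.value, tolerance = 1e-10)
  expect_error(spearman_corr(rep(1, 10), 1:10), "constant")
})

test_that("the specificity screen isolates confound relationships and missingness", {
  set.seed(18)
  n <- 60
  pred <- rnorm(n)
  phen <- data.frame(
    age = pred,                       # deliberately identical
    mean_fd = rnorm(n),
    education = rnorm(n),
    moca = c(rnorm(n - 8), rep(NA, 8)),
    sex = sample(c("M", "F"), n, replace = TRUE)
  )
  scr <- specificity_screen(pred, phen)
  rows <- scr$correlations
  expect_equal(rows$r[rows$variable == "age"], 1)
  expect_equal(rows$n[rows$variable == "moca"], n - 8)
  expect_equal(rows$n_missing[rows$variable == "moca"], 8)
  expect_false(is.null(scr$sex_test))

  # score-independent confounds stay weakly correlated in most cohorts
  weak <- 0
  for (sd in 1:6) {
    set.seed(400 + sd)
    p2 <- rnorm(100)
    ph2 <- data.frame(age = rnorm(100), mean_fd = rnorm(100),
                      education = rnorm(100), moca = rnorm(100))
    if (all(abs(specificity_screen(p2, ph2)$correlations$r) < 0.3)) {
      weak <- weak + 1
    }
  }
  expect_gt(weak, 3)
})

test_that("permutation p is invariant to relabeling the subjects", {
  co <- small_planted_cohort(seed = 19, n_subjects = 20, n_rois = 8,
                             n_timepoints = 60, n_edges = 3)
  stk <- build_connectome(co$series, "discordance", q = 0.9)
  perm <- rev(seq_len(20))
  stk_r <- stk
  stk_r$values <- stk_r$values[perm, ]
  p1 <- permutation_test(stk, co$phenotypes$score, co$phenotypes$age,
                         p_threshold = 0.05, n_perm = 30, seed = 3)
  p2 <- permutation_test(stk_r, co$phenotypes$score[perm],
                         co$phenotypes$age[perm],
                         p_threshold = 0.05, n_perm = 30, seed = 3)
  expect_equal(p1$r_true, p2$r_true, tolerance = 1e-10)
})
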