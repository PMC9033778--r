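test_that("partial correlation matches its definition and the residualization oracle", {
  set.seed(1)
  x <- rnorm(20); y <- rnorm(20); z <- rnorm(20)
  pc <- partial_correlation(x, y, z)
  expect_equal(pc$r_partial, residualized_partial_cor(x, y, z),
               tolerance = 1e-10)

  # covariate orthogonal to both -> plain Pearson r
  zo <- residuals(lm(rnorm(20) ~ x + y))
  pc2 <- partial_correlation(x, y, zo)
  expect_equal(pc2$r_partial, cor(x, y), tolerance = 1e-10)

  pc3 <- partial_correlation(x, x, z)
  expect_equal(pc3$r_partial, 1)
  expect_lt(pc3$p_value, 1e-12)

  expect_error(partial_correlation(x[1:3], y[1:3], z[1:3]), "4")
  expect_error(partial_correlation(x, rep(1, 20), z), "constant")
})

test_that("feature selection splits significant edges by sign and respects the threshold", {
  co <- small_planted_cohort(seed = 2)
  stk <- build_connectome(co$series, "discordance", q = 0.9)
  sel <- select_features(stk, co$phenotypes$score, co$phenotypes$age,
                         p_threshold = 0.001)
  expect_false(any(sel$positive_mask & sel$negative_mask))
  expect_true(all(sel$p_value[sel$positive_mask] < 0.001))
  expect_true(all(sel$partial_r[sel$positive_mask] > 0))
  expect_true(all(sel$partial_r[sel$negative_mask] < 0))

  # planted edges land in the positive mask of the discordance stack
  gkey <- paste(co$ground_truth$signature_edges[, 1],
                co$ground_truth$signature_edges[, 2])
  skey <- paste(stk$edge_index[, 1], stk$edge_index[, 2])
  expect_true(all(sel$positive_mask[match(gkey, skey)]))

  # a vanishing threshold empties both masks
  sel0 <- select_features(stk, co$phenotypes$score, co$phenotypes$age,
                          p_threshold = 1e-300)
  expect_equal(sum(sel0$positive_mask) + sum(sel0$negative_mask), 0)

  expect_error(select_features(stk, co$phenotypes$score[-1],
                               co$phenotypes$age[-1]), "aligned")
  expect_error(select_features(stk, rep(1, 40), co$phenotypes$age),
               "constant")
})

test_that("under a null cohort the per-edge selection rate matches the level", {
  hits <- 0
  total <- 0
  for (sd in 1:10) {
    co <- null_cohort(seed = 100 + sd, n_subjects = 50, n_rois = 20,
                      n_timepoints = 80)
    stk <- build_connectome(co$series, "discordance", q = 0.9)
    sel <- select_features(stk, co$phenotypes$score, co$phenotypes$age,
                           p_threshold = 0.01)
    hits <- hits + sum(sel$positive_mask) + sum(sel$negative_mask)
    total <- total + length(sel$p_value)
  }
  rate <- hits / total
  # 3 binomial SDs around 0.01 (edges within a cohort are weakly dependent)
  expect_lt(abs(rate - 0.01), 4 * sqrt(0.01 * 0.99 / total))
})

test_that("single-component PLS matches NIPALS and degenerates to OLS", {
  set.seed(4)
  X <- matrix(rnorm(20 * 5), 20, 5)
  y <- drop(X %*% c(1, -2, 0, 0.5, 1)) + rnorm(20)
  fit <- fit_pls1(X, y)
  oracle <- nipals_pls1(X, y)
  expect_equal(fit$fitted, oracle$fitted, tolerance = 1e-8)

  # one feature: identical to simple least squares
  x1 <- X[, 1, drop = FALSE]
  f1 <- fit_pls1(x1, y)
  ols <- lm(y ~ x1)
  expect_equal(unname(f1$intercept), unname(coef(ols)[1]), tolerance = 1e-10)
  expect_equal(unname(f1$coefficients), unname(coef(ols)[2]),
               tolerance = 1e-10)

  # duplicated column leaves the fitted values unchanged
  fdup <- fit_pls1(cbind(x1, x1), y)
  expect_equal(fdup$fitted, f1$fitted, tolerance = 1e-10)

  expect_error(fit_pls1(X, rep(2, 20)), "constant")
  expect_error(fit_pls1(X[1:2, ], y[1:2]), "3 subjects")
})

test_that("scaled PLS differs from centered-only but keeps original-scale coefficients", {
  set.seed(9)
  X <- cbind(rnorm(30), rnorm(30) * 100)
  y <- X[, 1] + 0.01 * X[, 2] + rnorm(30, sd = 0.5)
  f_c <- fit_pls1(X, y, scale = FALSE)
  f_s <- fit_pls1(X, y, scale = TRUE)
  expect_false(isTRUE(all.equal(f_c$fitted, f_s$fitted)))
  expect_equal(f_s$fitted, f_s$intercept + drop(X %*% f_s$coefficients))
})

test_that("LOOCV keeps folds pure and recovers a noise-free linear signal", {
  co <- small_planted_cohort(seed = 5)
  stk <- build_connectome(co$series, "discordance", q = 0.9)

  # noise-free response constructed from one edge
  y_lin <- 10 + 50 * stk$values[, 3]
  cv_lin <- suppressWarnings(
    cpm_loocv(stk, y_lin, co$phenotypes$age, p_threshold = 0.001)
  )
  expect_gt(cv_lin$eval$r, 0.99)
  expect_equal(length(cv_lin$predicted), nrow(stk$values))
  expect_equal(length(cv_lin$fold_edges), nrow(stk$values))

  # fold purity: corrupting the held-out subject's connectivity must not
  # change that fold's selected edge set
  cv <- suppressWarnings(
    cpm_loocv(stk, co$phenotypes$score, co$phenotypes$age)
  )
  stk2 <- stk
  k <- 7
  stk2$values[k, ] <- rev(stk2$values[k, ])
  cv2 <- suppressWarnings(
    cpm_loocv(stk2, co$phenotypes$score, co$phenotypes$age)
  )
  expect_equal(cv$fold_masks[k, ], cv2$fold_masks[k, ])
})

test_that("LOOCV on score-independent connectivity is mostly no better than the mean", {
  nonpos <- 0
  for (sd in 1:10) {
    co <- null_cohort(seed = 300 + sd, n_subjects = 25, n_rois = 12,
                      n_timepoints = 60)
    stk <- build_connectome(co$series, "discordance", q = 0.9)
    cv <- suppressWarnings(
      cpm_loocv(stk, co$phenotypes$score, co$phenotypes$age,
                p_threshold = 0.05)
    )
    if (cv$eval$r_squared <= 0) nonpos <- nonpos + 1
  }
  expect_gt(nonpos, 5)
})

test_that("prediction evaluation reproduces the R-squared definition", {
  ev <- evaluate_predictions(c(1, 2, 3), c(1, 2, 3))
  expect_equal(ev$r, 1)
  expect_equal(ev$r_squared, 1)

  obs <- c(4, 8, 6, 2)
  ev2 <- evaluate_predictions(rep(mean(obs), 4), obs)
  expect_equal(ev2$r_squared, 0)
  expect_true(is.na(ev2$r))

  ev3 <- evaluate_predictions(c(3, 2, 1), c(1, 2, 3))
  expect_equal(ev3$r, -1)
  expect_equal(ev3$sse, 8)
  expect_equal(ev3$sst, 2)
  expect_equal(ev3$r_squared, -3)
})

test_that("consensus edges use exact count thresholds and nest monotonically", {
  # an edge present in 66 of 71 folds misses the 95% cut (needs 68)
  masks <- matrix(FALSE, 71, 6)   # 6 edges = 4 ROIs
  masks[1:66, 2] <- TRUE
  masks[, 5] <- TRUE
  cons95 <- consensus_edges(masks, 0.95)
  expect_equal(nrow(cons95), 1)
  expect_equal(unname(cons95[1, ]), c(1, 3))  # edge 5 of edge_index(4)
  cons90 <- consensus_edges(masks, 0.90)      # needs 64 -> edge 2 back in
  expect_equal(nrow(cons90), 2)
  cons100 <- consensus_edges(masks, 1)
  k100 <- paste(cons100[, 1], cons100[, 2])
  k95 <- paste(cons95[, 1], cons95[, 2])
  k90 <- paste(cons90[, 1], cons90[, 2])
  expect_true(all(k100 %in% k95) && all(k95 %in% k90))

  # identical folds reproduce the common set at any fraction
  same <- matrix(rep(c(TRUE, FALSE, TRUE, FALSE, FALSE, TRUE), each = 10),
                 10, 6)
  for (f in c(0.9, 0.95, 1)) {
    expect_equal(nrow(consensus_edges(same, f)), 3)
  }
  expect_error(consensus_edges(matrix(FALSE, 0, 6), 0.95), "empty")
})

test_that("a fixed-parameter model reproduces itself and round-trips through JSON", {
  co <- small_planted_cohort(seed = 6)
  stk <- build_connectome(co$series, "discordance", q = 0.9)
  model <- cpm_train(stk, co$phenotypes$score, co$phenotypes$age)

  # in-sample application reproduces the fitted values
  refit <- fit_pls1(
    stk$values[, paste(stk$edge_index[, 1], stk$edge_index[, 2]) %in%
                 paste(model$edges[, 1], model$edges[, 2]), drop = FALSE],
    co$phenotypes$score
  )
  expect_equal(predict(model, stk), refit$fitted)

  path <- tempfile(fileext = ".json")
  write_cpm_model(model, path)
  model2 <- read_cpm_model(path)
  expect_identical(predict(model2, stk), predict(model, stk))

  # training optimism: in-sample r beats LOOCV r
  cv <- suppressWarnings(cpm_loocv(stk, co$phenotypes$score,
                                   co$phenotypes$age))
  expect_gt(cor(predict(model, stk), co$phenotypes$score), cv$eval$r)
})

test_that("model application enforces parcellation, profile and q agreement", {
  co <- small_planted_cohort(seed = 8)
  stk <- build_connectome(co$series, "discordance", q = 0.9)
  model <- cpm_train(stk, co$phenotypes$score, co$phenotypes$age)

  co2 <- small_planted_cohort(seed = 88)
  new_match <- build_connectome(co2$series, "discordance", q = 0.9)
  preds <- predict(model, new_match)
  expect_gt(cor(preds, co2$phenotypes$score), 0)  # generalizes

  small <- build_connectome(
    lapply(co2$series, function(m) m[, 1:10]), "discordance", q = 0.9
  )
  expect_error(predict(model, small), "parcellation")
  wrong_prof <- build_connectome(co2$series, "accordance", q = 0.9)
  expect_error(predict(model, wrong_prof), "profile")
  wrong_q <- build_connectome(co2$series, "discordance", q = 0.85)
  expect_error(predict(model, wrong_q), "quantile")

  # no selectable edges -> error at construction time
  expect_error(
    cpm_train(stk, co$phenotypes$score, co$phenotypes$age,
              p_threshold = 1e-300),
    "no edges"
  )
})

test_that("parameter sweeps cover the grid and support paired comparisons", {
  co <- small_planted_cohort(seed = 10, n_subjects = 30, n_rois = 10,
                             n_timepoints = 60, n_edges = 4)
  sw <- parameter_sweep(
    co$series, co$phenotypes$score, co$phenotypes$age,
    q_grid = c(0.85, 0.9), p_grid = c(0.01, 0.05),
    models = list(c("discordance", "positive"), c("accordance", "negative"))
  )
  expect_equal(dim(sw$r), c(2, 2, 2))
  cmpr <- compare_sweep_models(sw, "discordance_positive",
                               "accordance_negative")
  expect_equal(cmpr$df, 3)

  # a (jittered) offset between models fixes the sign of t
  sw2 <- sw
  set.seed(1)
  sw2$r[, , 2] <- sw2$r[, , 1] - 0.1 + rnorm(4, sd = 1e-3)
  cmp2 <- compare_sweep_models(sw2, "discordance_positive",
                               "accordance_negative")
  expect_gt(cmp2$t, 0)
  sw2$r[, , 2] <- sw2$r[, , 1]
  expect_error(compare_sweep_models(sw2, "discordance_positive",
                                    "accordance_negative"), "variance")

  expect_error(parameter_sweep(co$series, co$phenotypes$score,
                               co$phenotypes$age, q_grid = numeric(0)),
               "empty")
})

test_that("the default stability grids give 110 cells and a df-109 paired test", {
  co <- small_planted_cohort(seed = 12, n_subjects = 30, n_rois = 10,
                             n_timepoints = 80, n_edges = 4)
  sw <- suppressWarnings(parameter_sweep(
    co$series, co$phenotypes$score, co$phenotypes$age,
    models = list(c("discordance", "positive"), c("accordance", "negative"))
  ))
  expect_equal(dim(sw$r)[1] * dim(sw$r)[2], 110)  # 11 q values x 10 p values
  cmpr <- compare_sweep_models(sw, "discordance_positive",
                               "accordance_negative")
  expect_equal(cmpr$df, 109)
})
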