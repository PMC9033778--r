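#' Configuration for a synthetic antagonistic cohort
#'
#' Bundles and validates the generator parameters. The defaults emulate
#' a hospital movement-disorder cohort: motor scores with mean 26 and
#' SD 14 (clinically plausible UPDRS-III territory), ages around 60
#' with a mild positive correlation with the score, 200-volume scans,
#' and AR(1) temporal autocorrelation in every ROI series.
#'
#' @param n_subjects,n_rois,n_timepoints Cohort dimensions
#'   (`n_timepoints >= 30`).
#' @param signature_edges Integer matrix (or list of length-2 vectors)
#'   of 0-based node pairs `i < j` carrying the planted behavior-coupled
#'   anti-phase signal; default: 20 random disjoint-free pairs are NOT
#'   chosen here — pass explicitly or use [default_signature_edges()].
#' @param coupling_base Baseline anti-coupling mixing weight
#'   (lambda0 >= 0).
#' @param coupling_slope Gain of the anti-coupling weight per SD of the
#'   score (lambda1); the per-subject weight is
#'   `lambda_s = lambda0 + lambda1 * (score_s - mean) / sd`.
#' @param noise_sd SD of the independent AR(1) noise in every node
#'   (> 0).
#' @param ar_coefficient Lag-1 autocorrelation in \[0, 1) shared by
#'   latent signals and noise.
#' @param score_mean,score_sd Behavioral score distribution.
#' @param age_score_corr Correlation between age and score in (-1, 1).
#' @param hy_probs Named numeric vector of probabilities over the H&Y
#'   levels 1, 1.5, 2, 2.5, 3, 4, 5 used to cut the score quantiles
#'   into stages; must sum to 1.
#' @param seed Integer seed; all randomness in [generate_cohort()] flows
#'   from it.
#' @return Object of class `cohort_config` (validated list).
#' @export
cohort_config <- function(n_subjects = 100,
                          n_rois = 60,
                          n_timepoints = 200,
                          signature_edges = default_signature_edges(n_rois),
                          coupling_base = 1,
                          coupling_slope = 0.8,
                          noise_sd = 1,
                          ar_coefficient = 0.3,
                          score_mean = 26,
                          score_sd = 14,
                          age_score_corr = 0.3,
                          hy_probs = c("1" = 0.15, "1.5" = 0.10,
                                       "2" = 0.22, "2.5" = 0.25,
                                       "3" = 0.21, "4" = 0.05,
                                       "5" = 0.02),
                          seed = 1) {
  if (is.list(signature_edges)) {
    signature_edges <- do.call(rbind, signature_edges)
  }
  signature_edges <- matrix(as.integer(signature_edges), ncol = 2L,
                            dimnames = list(NULL, c("i", "j")))
  if (n_subjects < 1 || n_rois < 2 || n_timepoints < 30) {
    stop("invalid dimensions (need n_subjects >= 1, n_rois >= 2, ",
         "n_timepoints >= 30)")
  }
  if (nrow(signature_edges) > 0L) {
    if (any(signature_edges < 0L) || any(signature_edges >= n_rois)) {
      stop("signature edge references a node outside 0..n_rois-1")
    }
    if (any(signature_edges[, 1L] >= signature_edges[, 2L])) {
      stop("signature edges must have distinct nodes with i < j")
    }
  }
  if (coupling_base < 0) stop("coupling_base must be >= 0")
  if (noise_sd <= 0) stop("noise_sd must be > 0")
  if (ar_coefficient < 0 || ar_coefficient >= 1) {
    stop("ar_coefficient must lie in [0, 1)")
  }
  if (abs(age_score_corr) >= 1) stop("age_score_corr must lie in (-1, 1)")
  hy_levels <- c(1, 1.5, 2, 2.5, 3, 4, 5)
  if (length(hy_probs) != 7L || abs(sum(hy_probs) - 1) > 1e-8) {
    stop("hy_probs must give 7 probabilities summing to 1")
  }
  structure(
    list(n_subjects = as.integer(n_subjects),
         n_rois = as.integer(n_rois),
         n_timepoints = as.integer(n_timepoints),
         signature_edges = signature_edges,
         coupling_base = coupling_base,
         coupling_slope = coupling_slope,
         noise_sd = noise_sd,
         ar_coefficient = ar_coefficient,
         score_mean = score_mean,
         score_sd = score_sd,
         age_score_corr = age_score_corr,
         hy_levels = hy_levels,
         hy_probs = unname(hy_probs),
         seed = as.integer(seed)),
    class = "cohort_config"
  )
}

#' Default planted signature edges
#'
#' Deterministic set of 20 node pairs spread over the parcellation:
#' pairs (2k, 2k+1) for k = 0..19 (requires `n_rois >= 40`), a
#' convention that keeps planted edges disjoint so each carries an
#' independent latent signal.
#'
#' @param n_rois Parcellation size.
#' @param n_edges Number of planted edges (default 20).
#' @return Integer matrix with columns `i`, `j`.
#' @export
default_signature_edges <- function(n_rois, n_edges = 20L) {
  n_edges <- min(n_edges, n_rois %/% 2L)
  k <- seq_len(n_edges) - 1L
  cbind(i = 2L * k, j = 2L * k + 1L)
}

# stationary AR(1) series, sd `s`, lag-1 coefficient `phi`
.ar1 <- function(n, phi, s) {
  e <- stats::rnorm(n)
  x <- numeric(n)
  x[1L] <- e[1L]
  if (n > 1L) for (t in 2:n) x[t] <- phi * x[t - 1L] + sqrt(1 - phi^2) * e[t]
  s * x
}

#' Generate a synthetic cohort with planted antagonistic edges
#'
#' Draws one latent AR(1) signal per signature edge and per subject;
#' node `i` of the edge receives the latent unscaled, node `j`
#' receives `-lambda_s` times the SAME latent (an anti-phase copy), on
#' top of independent AR(1) noise, with
#' `lambda_s = coupling_base + coupling_slope * standardized(score_s)`.
#' A negative `lambda_s` (a low-scoring subject when
#' `coupling_base = 0`) turns the copy in-phase, so the same planted
#' edges also carry an accordance signal that DECREASES with the score.
#' High-scoring subjects therefore carry stronger anti-phase coupling
#' on the signature edges, so their discordance there increases
#' stochastically with the score; non-signature node pairs share no
#' latent signal. Age is drawn with the configured correlation to the
#' score; the H&Y stage is assigned by score quantile through the
#' configured level probabilities (so stage analysis has signal); sex,
#' education, MoCA and mean FD are independent of the score.
#'
#' Randomness is drawn in a fixed documented order from the single
#' config seed: (1) scores, (2) age noise, (3) sex, (4) education,
#' (5) MoCA, (6) mean FD, then per subject (7) edge latents in edge
#' order and (8) node noise in node order. Identical configs therefore
#' give bit-identical cohorts.
#'
#' @param config A [cohort_config()].
#' @return List with `series` (named list of timepoints x ROIs
#'   matrices), `phenotypes` (data frame: subject_id, score, age, sex,
#'   education, moca, hy, mean_fd, site), `ground_truth` (list:
#'   signature_edges, coupling, scores).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  old_seed <- .save_rng()
  on.exit(.restore_rng(old_seed), add = TRUE)
  set.seed(config$seed)
  n <- config$n_subjects
  R <- config$n_rois
  Tn <- config$n_timepoints
  edges <- config$signature_edges

  score <- stats::rnorm(n, config$score_mean, config$score_sd)
  zs <- (score - mean(score)) / stats::sd(score)
  rho <- config$age_score_corr
  age <- 60 + 10 * (rho * zs + sqrt(1 - rho^2) * stats::rnorm(n))
  sex <- ifelse(stats::runif(n) < 0.55, "M", "F")
  education <- pmin(22, pmax(0, round(stats::rnorm(n, 9, 4))))
  moca <- pmin(30, pmax(0, round(stats::rnorm(n, 22, 5))))
  mean_fd <- pmax(0.01, stats::rnorm(n, 0.11, 0.04))

  # H&Y by score quantile: rank-based cut at cumulative probabilities
  cum <- cumsum(config$hy_probs)
  qranks <- (rank(score, ties.method = "first") - 0.5) / n
  hy <- config$hy_levels[findInterval(qranks, c(0, cum),
                                      rightmost.closed = TRUE)]

  lambda <- config$coupling_base + config$coupling_slope * zs
  if (any(!is.finite(lambda))) stop("coupling produced non-finite values")

  series <- vector("list", n)
  for (s in seq_len(n)) {
    x <- matrix(0, Tn, R)
    if (nrow(edges) > 0L) {
      for (e in seq_len(nrow(edges))) {
        latent <- .ar1(Tn, config$ar_coefficient, 1)
        x[, edges[e, 1L] + 1L] <- x[, edges[e, 1L] + 1L] + latent
        x[, edges[e, 2L] + 1L] <- x[, edges[e, 2L] + 1L] - lambda[s] * latent
      }
    }
    noise <- vapply(seq_len(R),
                    function(r) .ar1(Tn, config$ar_coefficient,
                                     config$noise_sd),
                    numeric(Tn))
    series[[s]] <- x + noise
  }
  ids <- sprintf("sub%03d", seq_len(n))
  names(series) <- ids
  list(
    series = series,
    phenotypes = data.frame(
      subject_id = ids, score = score, age = age, sex = sex,
      education = education, moca = moca, hy = hy, mean_fd = mean_fd,
      site = "synthetic", stringsAsFactors = FALSE
    ),
    ground_truth = list(signature_edges = edges,
                        coupling = lambda,
                        scores = score)
  )
}

#' Random node-to-network assignment table
#'
#' Assigns every node exactly one of `n_networks` labels, guaranteeing
#' each label is used at least once (one node per label first, the rest
#' uniformly), then shuffles node order assignment.
#'
#' @param n_rois Number of nodes.
#' @param n_networks Number of networks, `1 <= n_networks <= n_rois`.
#' @param seed Integer seed.
#' @return Data frame with columns `node_id` (0-based) and `network`
#'   (labels `"N01"`, `"N02"`, ...).
#' @export
make_network_assignment <- function(n_rois, n_networks, seed = 1) {
  if (n_networks < 1L || n_networks > n_rois) {
    stop("need 1 <= n_networks <= n_rois")
  }
  old_seed <- .save_rng()
  on.exit(.restore_rng(old_seed), add = TRUE)
  set.seed(seed)
  labels <- sprintf("N%02d", seq_len(n_networks))
  lab <- c(labels, sample(labels, n_rois - n_networks, replace = TRUE))
  lab <- sample(lab)
  data.frame(node_id = 0:(n_rois - 1L), network = lab,
             stringsAsFactors = FALSE)
}
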