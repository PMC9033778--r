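---
title: "Antagonistic connectivity and connectome-based prediction: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Antagonistic connectivity and connectome-based prediction: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(antagnet)
```

## The scientific problem

In Parkinson's disease (PD), motor impairment is accompanied by widespread
*decoupling* of brain activity: regions that normally fluctuate together
drift out of phase, plausibly as a downstream effect of dopamine depletion.
The ordinary Pearson correlation between two regions' BOLD time series
summarizes coupling and anti-coupling in a single signed number, which
blurs exactly the distinction that matters here. This package works with a
decomposition of functional connectivity (FC) into two nonnegative
components defined on *extreme events* of the signal:

- **accordance** — how often two regions reach extremes *in the same
  direction* at the same time (in-phase synchronization), and
- **discordance** — how often they reach *opposite* extremes together
  (antagonistic, out-of-phase interaction).

Discordance-based connectomes are then used to predict a continuous motor
severity score (a UPDRS-III-like scale) per subject via connectome-based
predictive modeling (CPM), and the resulting model is interrogated at the
network level and across disease stages.

## Connectivity model

Each ROI time course is z-scored with its own mean and **sample** standard
deviation (denominator $n-1$; the convention is not universal, so it is
fixed and documented here). For a quantile $q \in (0.5, 1)$ (default
$q = 0.9$), the normalized series $z_t$ is split into two binary indicator
series,

$$u_t = \mathbb{1}\{z_t \ge \Phi^{-1}(q)\}, \qquad
  l_t = \mathbb{1}\{z_t \le \Phi^{-1}(1-q)\},$$

with $\Phi^{-1}$ the standard normal inverse CDF. A value exactly at a
threshold counts as an extreme. Because $q > 0.5$, $u$ and $l$ are
disjoint. For regions $i, j$ with $\sigma_i = \sqrt{u_i \cdot u_i + l_i
\cdot l_i}$ (the square root of the extreme-event count):

$$a_{ij} = \frac{u_i \cdot u_j + l_i \cdot l_j}{\sigma_i \sigma_j}, \qquad
  d_{ij} = \frac{u_i \cdot l_j + l_i \cdot u_j}{\sigma_i \sigma_j}.$$

Both lie in $[0,1]$, $a_{ii} = 1$, $d_{ii} = 0$, and
$a_{ij} + d_{ij} \le 1$ (Cauchy–Schwarz on disjoint indicators). Negating
one region's series swaps its $u$ and $l$ and hence swaps $a$ and $d$ on
all its edges; the test suite asserts this duality together with exact
agreement against a brute-force per-timepoint implementation.

Two deliberate conventions deserve note:

- **Theoretical vs empirical thresholds.** $\Phi^{-1}$ is applied as the
  *standard normal* quantile of the z-scored data, not as a per-series
  empirical quantile. Z-scored BOLD data are close enough to Gaussian for
  the two to nearly coincide; an `method = "empirical"` switch in
  `binarize_extremes()` and `build_connectome()` is provided for
  sensitivity analysis on heavy-tailed data.
- **Sign of discordance.** Part of the antecedent literature defines
  discordance with a negative sign. Here it is *nonnegative*, which is the
  form consistent with speaking of a "discordance **positive** network"
  (discordance increasing with symptom severity). Users comparing against
  other implementations should check this sign convention first.

Edges are vectorized in row-major upper-triangle order, 0-based, $i < j$:
$(0,1), (0,2), \dots$ — stated in every serialization. A 268-node
parcellation yields $268 \cdot 267 / 2 = 35{,}778$ edges.

## Predictive modeling

`cpm_train()` implements the CPM pipeline as one fitting function
returning a classed model object:

1. **Feature selection.** Every edge's connectivity is partially
   correlated with the score, controlling for age (the dominant FC
   confounder); edges with two-sided $p$ strictly below the threshold
   (default $0.001$) are split by the sign of the partial correlation into
   a positive and a negative network. Edges with $p$ exactly at the
   threshold, or partial correlation exactly zero, are excluded. Age is
   the only selection covariate by default, mirroring standard practice;
   the screen in `specificity_screen()` checks post hoc that predictions
   do not track other nuisance variables.
2. **Model building.** A single-component partial least squares (PLS1)
   regression maps the selected edges to the score. Predictors and
   response are mean-centered but **not** variance-scaled by default: the
   features share a common connectivity scale, and unit-scaling would
   up-weight low-variance edges; `scale = TRUE` is available. With one
   component the solution is closed-form ($w \propto X^\top y$), and with
   one selected edge it degenerates to simple least squares — both facts
   are exploited as test oracles (an independently coded iterative NIPALS
   implementation serves as the reference).
3. **Validation.** `cpm_loocv()` runs leave-one-out cross-validation with
   selection *and* fitting redone inside every fold, so the held-out
   subject never influences the model that predicts them (fold purity is
   asserted by perturbation in the tests). Performance is summarized by
   Pearson $r$ between predicted and observed scores and by the predicted
   $R^2 = 1 - \mathrm{SSE}/\mathrm{SST}$, with SST taken about the mean of
   the observed vector being evaluated (the centering constant is
   otherwise ambiguous); this out-of-sample $R^2$ can be negative.
4. **Consensus and transfer.** `consensus_edges()` retains edges selected
   in at least a fraction of folds (exact count comparison:
   $\ge \lceil f \cdot n \rceil$; 0.90/0.95/1.00 are the customary
   robustness levels), and `predict()` applies a frozen model to an
   independent cohort, refusing any mismatch in parcellation size,
   profile, or $q$.

**Empty folds.** At strict thresholds on small cohorts a fold can select
zero edges. Aborting would make LOOCV undefined, so the fold predicts the
training mean of the score and the event is reported in a loud warning and
recorded in the result object. Whether this ever occurs in a given
analysis is therefore always visible.

## Inference

- **Permutation test.** The score vector is shuffled and the *entire*
  LOOCV pipeline is rerun per permutation (selection inside folds
  included); $p$ is the fraction of null $r$ values $\ge$ the true $r$.
  This estimator can return exactly 0, so the add-one estimator
  $(k+1)/(B+1)$ is reported alongside. Permutations where the null
  predictions are constant (undefined $r$) are counted as maximally
  unfavorable to rejection. Default $B = 10{,}000$; the calibration
  experiments in the test suite use 99 permutations across 50 replicate
  null cohorts, which keeps the suite fast while leaving the
  Kolmogorov–Smirnov uniformity check well powered.
- **Steiger's z.** Candidate models are compared through their dependent
  correlations with the same observed scores, using the pooled-$\bar r$
  variant of Steiger's test (the common software default; the variant
  choice is otherwise underdetermined). Monte-Carlo calibration under the
  null is part of the acceptance suite.
- **Group comparisons.** 2×2 chi-square uses the Yates continuity
  correction by default — the setting that uniquely reproduces the printed
  sex-ratio p-values (0.012, 0.003) of the reference demographic table.
  For continuous variables a summary-statistic two-sample t-test is
  provided in pooled and Welch variants: the published motor-score
  comparison reproduces under the pooled form, while the published age
  comparison matches Welch better; printed-rounding of means and SDs
  prevents a definitive call, so both are exposed and neither is declared
  canonical.
- **Spearman correlation** uses mid-ranks and the t approximation, the
  behavior of `cor.test(..., exact = FALSE)`, reimplemented in vector
  form and cross-checked against it.

## Network-level aggregation

`aggregate_network_weights()` sums each model edge's coefficient into its
(network, network) cell and into both endpoint nodes. The default uses
**absolute** coefficients: the customary summaries ("x% of predictive
weight between networks") require a nonnegative mass, and a single-sign
network's coefficients are typically same-signed anyway; `mode = "signed"`
is retained for inspection. Within-network mass counts once — the
upper-triangle-plus-diagonal sum equals the total coefficient mass
exactly (asserted to $10^{-12}$). `top_network_pairs()` ranks nonzero
pairs and returns the top $\lceil f K \rceil$, breaking ties
lexicographically so results are deterministic.

## Stage-wise residual analysis

Subjects are grouped by Hoehn–Yahr stage: mild (1, 1.5, 2), moderate
(2.5, 3), severe (4, 5); any other value is an error rather than silently
binned. The residual is defined as **observed − predicted**: with this
convention a group whose scores are over-predicted shows a *negative*
one-sample t — the orientation in which an early-stage connectivity
signature "running ahead" of clinical signs manifests as $t < 0$ in the
mild group. Spearman correlations of observed, predicted, and residual
scores against stage, and pairwise group t-tests with a fixed Bonferroni
factor of 3 (the number of pairs), complete the report.

## The synthetic cohort generator

No generative model accompanies the real cohorts, so `generate_cohort()`
emulates the *data regime* rather than any estimate of it: multi-subject
ROI time series (defaults: 100 subjects, 60 ROIs, 200 volumes — the scan
lengths of the reference cohorts are 170–240 volumes) in which a
configurable set of signature edges carries behavior-coupled anti-phase
structure. For each signature edge and subject, one latent AR(1) signal is
drawn; node $i$ receives it unscaled and node $j$ receives
$-\lambda_s \times$ the same latent on top of independent AR(1) noise,
with

$$\lambda_s = \lambda_0 + \lambda_1 \frac{y_s - \bar y}{s_y}.$$

Defaults: $\lambda_0 = 1$, $\lambda_1 = 0.8$, noise SD 1, AR coefficient
0.3 (a typical BOLD lag-1 autocorrelation at a ~2 s sampling interval).
$\lambda_0 = 1$ makes the default cohort genuinely *antagonistic*:
anti-phase coupling is present in essentially every subject and grows with
severity. With $\lambda_0 = 0$ (used in one recovery experiment) half the
cohort has a negative $\lambda_s$, i.e. **in-phase** coupling that
*decreases* with the score — which is exactly what plants a secondary
accordance-negative signal, so both model families have something to find,
but the discordance-positive model dominates only when the cohort is
antagonism-dominated.

Phenotypes: scores are Gaussian (mean 26, SD 14 — plausible UPDRS-III
territory); age (mean 60, SD 10) is drawn with a configurable correlation
to the score (default 0.3) to make the age-controlled partial correlation
meaningfully different from the raw one; H&Y stage is assigned by score
quantile through configurable level probabilities (defaults approximating
a mild/moderate/severe split of roughly 47/46/7%), so stage analysis has
signal by construction; sex, education, MoCA and mean FD are drawn
independently of the score, which is what makes the specificity screen a
true negative control. All randomness flows from the single config seed
in a fixed documented stream order (scores, age, sex, education, MoCA,
FD, then per-subject latents and noise), so cohorts are bit-reproducible.

What the generator does **not** emulate: hemodynamic response shapes,
scanner noise spectra, head-motion artifacts, site effects, or spatial
autocorrelation between ROIs. Passing recovery tests therefore
demonstrates that the pipeline's machinery is correct and calibrated — not
that comparable performance is attainable on real patient data.

## Numerical choices and degenerate inputs

- Constant ROI series are an error naming the ROI (z-scoring is
  undefined); a region with zero extreme events ($\sigma = 0$) is an
  error naming the subject and region.
- Partial correlations are clamped to $[-1, 1]$ against floating-point
  overshoot; constant edges (possible for discordance at strict $q$) get
  $r = 0$, $p = 1$, and are never selected.
- `fit_pls1()` refuses an all-zero $X^\top y$ (no covariance direction)
  and a constant response.
- The paired sweep comparison (`compare_sweep_models()`) refuses
  zero-variance differences, where t is undefined.
- Tie-breaks (network-pair ranking) and boundary rules (threshold
  equality in binarization, strict `>` in the motion gate, strict `<` in
  selection) are each fixed to one documented convention and tested at
  the boundary.

## Problem sizes used in the test and acceptance runs

The packaged experiments are sized for a single CPU: recovery runs use
the full default cohort (100 subjects × 60 ROIs × 200 timepoints, 5
seeds); permutation calibration uses 50 null cohorts of 30 subjects × 16
ROIs × 60 timepoints with 99 permutations each; Steiger calibration uses
2,000 trivariate-normal replicates at $n = 100$. These sizes keep every
statistical check well-powered while the whole suite completes in about
two minutes.

## Known limitations

- Single-component PLS only; multi-component fits, ridge/SVR learners and
  k-fold variants are out of scope by design.
- The permutation test reruns the full pipeline and therefore scales
  linearly in $B \times n_\text{subjects}$ LOOCV fits; at the default
  $B = 10{,}000$ on large cohorts this is an overnight computation.
- The generator's effect sizes are calibration targets for the pipeline,
  not estimates of real PD effect sizes; absolute $r$ values obtained on
  synthetic cohorts say nothing about attainable clinical performance.
- Missing phenotype values are handled by pairwise deletion with logged
  counts; no imputation is attempted.
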