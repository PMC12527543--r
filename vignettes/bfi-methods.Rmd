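---
title: "One-shot Bayesian federated inference for multicenter GLMs: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{One-shot Bayesian federated inference for multicenter GLMs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bfiglm)
```

## The problem

Regression models for clinical outcomes are routinely starved of data: each
hospital or registry holds too few subjects relative to the number of
candidate covariates, and privacy regulation blocks pooling the subject-level
rows. Bayesian federated inference (BFI) addresses this with a *one-shot*
protocol: each of $L$ centers fits its model once on its own data and shares
only a small summary — the parameter estimate, its curvature matrix, the
prior it used, and the sample size. A central analyst combines the $L$
summaries into an approximation of the estimate that a maximum-a-posteriori
(MAP) analysis of the pooled data would have produced. No subject-level data
move, and no iterative cycling between centers is needed; a late-joining
center can be folded in afterwards and yields exactly the same estimate as
if it had been present from the start.

## Model and estimator

Within center $\ell$, subjects $(x_{\ell i}, y_{\ell i})$ follow a
generalized linear model with linear predictor $x_{\ell i}^\top\beta$.
Two families are implemented: Gaussian outcomes with identity link and error
variance $\sigma^2$, and binary outcomes with logit link. The full parameter
vector is $\theta = (\beta, \zeta)$, where $\zeta = \log\sigma^2$ for the
Gaussian family; the positive nuisance is estimated on the log scale so that
Newton updates are unconstrained and a Gaussian prior is meaningful for it.
All parameters carry zero-mean Gaussian priors with precision matrix
$\Lambda_\ell$ locally and $\Lambda$ in the (fictive) combined analysis —
the Bayesian counterpart of a ridge penalty.

Each center maximizes its penalized log-likelihood
$$\sum_i \ell(y_{\ell i} \mid x_{\ell i}^\top\beta, \zeta)
  - \tfrac12\,\theta^\top \Lambda_\ell\, \theta$$
by full Newton iteration with step-halving (`map_fit()`), and reports
$\hat\theta_\ell$ together with $\hat A_\ell$, the negative Hessian of its
log posterior at $\hat\theta_\ell$ (prior included). Approximating each
local log posterior by its second-order expansion around $\hat\theta_\ell$,
summing over centers, and replacing the sum of local priors by the combined
prior gives a quadratic surrogate of the pooled log posterior whose maximum
is available in closed form:
$$\hat A_{\mathrm{BFI}} = \sum_\ell \hat A_\ell - \sum_\ell \Lambda_\ell
  + \Lambda,
  \qquad
  \hat\theta_{\mathrm{BFI}} = \hat A_{\mathrm{BFI}}^{-1}
  \sum_\ell \hat A_\ell\, \hat\theta_\ell .$$
The inverse of $\hat A_{\mathrm{BFI}}$ estimates the covariance matrix of
the estimator; credible intervals are
$\hat\theta_k \pm z_{\alpha/2}\sqrt{[\hat A_{\mathrm{BFI}}^{-1}]_{kk}}$ and
Wald tests follow from the same Gaussian approximation.

Two properties anchor the implementation and its tests:

* **All-quadratic exactness.** For the Gaussian family with known variance
  the log posterior *is* quadratic, so the combination must reproduce pooled
  penalized least squares to numerical precision, whatever the data. This
  holds for the homogeneous, center-stratified and clustered modes, and is
  verified against closed-form ridge solutions on random problems.
* **Additivity.** The combination depends on the summaries only through
  sums, so any grouping or ordering of centers — including adding a center
  to a stored combination state (`bfi_accumulate()` / `bfi_finalize()`,
  `--add` on the command line) — reproduces the from-scratch result exactly.

## Heterogeneity structures

Centers rarely sample the same population. The aggregated model can declare
any subset of parameters center-specific or cluster-specific through
`het_spec()`:

* **Center-specific intercepts** absorb differences in outcome level
  (e.g. prevalence) between centers.
* **Center-specific slopes** express center-by-covariate interactions.
* **Center-specific `log_sigma2`** allows each center its own error
  variance; no separate code path exists — the nuisance is just another
  coordinate of $\theta$.
* **Cluster-specific intercepts** let groups of centers (e.g. small /
  medium / large hospitals) share one intercept. Within a center such a
  grouping variable is constant and inestimable; it only becomes estimable
  at combination time.

Internally, each declared parameter gets one copy per center (or cluster) in
a stacked parameter vector. Each center's quadratic expansion is mapped onto
the stacked coordinates — its own copies plus the shared block — which
assembles a block-arrow precision matrix; the local prior is subtracted and
the combined prior added with the parameter's marginal precision on every
copy, independently across copies. The system is solved by a dense Cholesky
factorization (the stacked dimension is at most a few dozen here, so the
Schur-complement economy of the block-arrow shape is not needed; a non-PD
matrix is a model-specification error and raises rather than being
pseudo-inverted or silently regularized). Setting the specification empty,
or one cluster for all centers, reduces the construction exactly to the
homogeneous formula; one cluster per center reduces it to the
center-stratified model.

Because the shared block borrows strength from *all* centers, the stratified
estimate of each center's own intercept is more precise than that center's
purely local estimate — a property checked empirically in the tests (20/20
simulated studies).

A **center-level continuous covariate** $z_\ell$ (say, hospital volume) is
constant within each center, so its effect hides in the center-specific
intercepts. `center_covariate_fit()` regresses the estimated intercepts on
$z_\ell$ by least squares; estimation uncertainty is propagated by drawing
each intercept from its approximate posterior
$N(\hat\gamma_\ell, sd_\ell^2)$ independently, refitting the line $B$ times
and averaging (draws are independent across centers — the recipe ignores
the posterior correlation induced through the shared slopes, which is the
standard simplification here). `B = 0` gives the plain line.

## Baselines and diagnostics

The natural one-shot competitor is the sample-size weighted average (WAV)
$\sum_\ell (n_\ell/n)\hat\theta_\ell$; under heterogeneity a cluster
parameter is averaged within its cluster and a center-specific parameter is
that center's own estimate. The log-variance is averaged on the log scale,
consistent with the parameter vector (the alternative — averaging
$\sigma^2$ — would make WAV depend on the nuisance parameterization). The
single-center baseline is the largest center's estimate, with lexicographic
tie-breaking; it is undefined when any parameter is center- or
cluster-specific, and the implementation refuses it.

Before assuming homogeneity one should look. Two interval diagnostics are
provided: the pairwise credible interval for the difference of a parameter
between two centers (independent local sds, so
$sd = \sqrt{sd_k^2 + sd_l^2}$), and a leave-one-out check comparing each
center's local estimate with the combination of all the others. Both use
local curvature-based standard deviations. No multiplicity correction is
applied across the $L$ comparisons — the report states their number and the
analyst judges; small centers give wide intervals, so a non-flag is not
evidence of homogeneity. The type-I error of the leave-one-out check is
verified to be near-nominal (about 5% at the 95% level) by simulation.

## Simulation harness

`scenario_config()` + `run_scenario()` reproduce a four-center logistic
study design: three covariates (two Gaussian, one Bernoulli), outcomes from
a logistic model, $B$ replicates, and per-coordinate mean squared error of
each one-shot estimator measured against the pooled-data MAP fit (MSE) and,
for the federated estimator, against the generating values (MSET). The
pooled reference under heterogeneity is the MAP fit of the dummy-coded
stacked design under the mapped combined prior (`pooled_het_fit()`).
Replicates whose fits fail to converge are redrawn with a fresh logged seed,
at most five times.

Defaults — true intercept $-1$, slopes $(0.5, -0.5, 1)$, covariate laws
$N(0,1)$, $N(1,2^2)$, Bernoulli$(1/2)$, prior precisions $0.01$ (nearly
flat) with $1$ as the stronger alternative, size presets $(50,100,150,200)$
and $(400,800,1200,1600)$, $B = 100$ — are this package's choices of a
realistic operating point for a moderate multicenter binary-outcome study;
they are configuration, not constants. Under covariate shift the per-center
laws spread over $\mu_1 \in [0, 1.5]$, $\sigma_2 \in [1, 2.5]$,
$p_3 \in [0.3, 0.7]$; center-specific true intercepts default to
$(-1.5, -1, -0.5, 0)$ and two-cluster intercepts to $(-1.5, -0.5)$.

`generate_nurses_like()` emulates a classic hierarchical teaching dataset:
job stress of roughly a thousand nurses in 25 hospitals. Per-hospital sizes
are uniform on 36–52; hospitals split into 9 small, 12 medium and 4 large;
age and experience are correlated Gaussians (correlation 0.6), gender and
ward type Bernoulli with per-hospital prevalences drawn from the ranges
observed in that dataset (fraction female 0.61–0.85, special-care ward
0.48–0.51, mean age 39.2–46.3, mean experience 14.9–18.5). The outcome is
Gaussian with a hospital-size cluster effect (baselines 3.7 / 4.3 / 5.0), a
per-hospital intercept perturbation (sd 0.2) and per-hospital error sd drawn
from $U(0.5, 1)$; these three values were calibrated once so that the
simulated per-hospital mean-stress range and residual-variance range match
the descriptive statistics of the emulated study (means 3.6–5.8, variances
0.17–1.16). Continuous columns are standardized across centers with
`standardize_centers()`, which reconstructs the pooled mean and sd exactly
from per-center moments — no rows are pooled to do it.

What the generator does *not* emulate: missingness, measurement error,
non-Gaussian stress distributions, informative cluster sizes, or
confounding between covariates and hospital effects. Passing tests on these
data show the federated arithmetic and the heterogeneity machinery behave
as designed — not that the model is adequate for any particular real
dataset.

`prediction_agreement_experiment()` mirrors the standard predictive check:
50 times, hold out ~10% of each center's subjects, fit locally on the rest,
combine, and predict the held-out outcomes; in parallel fit the pooled MAP
on the merged training rows and predict the same subjects. On the
standardized outcome scale the mean squared disagreement between the two
prediction sets is small when the aggregated model matches the heterogeneity
actually present, grows when heterogeneity is left unmodelled, and shrinks
again when subjects are re-randomized across centers
(`randomize_over_centers()`), pinning the disagreement on the heterogeneity
rather than on the federation itself.

## Numerical choices

* **Optimizer.** Full Newton on $(\beta, \zeta)$ jointly; tolerance $10^{-8}$
  on the max-abs gradient, at most 100 iterations. Non-PD Hessians far from
  the optimum (possible through the $\zeta$ block) are handled by escalating
  diagonal damping of the step, never of the reported curvature. The line
  search accepts any step that does not decrease the objective by more than
  $10^{-12}(|f|+1)$: near the optimum the objective plateaus in double
  precision while the gradient still contracts quadratically, and demanding
  strict increase would stall otherwise-converged fits.
* **Dropped constants.** The $2\pi$ terms of the Gaussian log-density are
  dropped everywhere, consistently, so only differences of log posteriors
  are meaningful — which is all the method ever uses.
* **Starting values.** Zero coefficients; $\zeta_0 = \log\widehat{var}(y)$.
* **Degenerate inputs.** An all-zero column, or a constant column alongside
  an intercept, with zero prior precision on it, is a genuinely flat
  posterior direction and raises `"flat direction"`. The same column with
  positive prior precision is allowed — the prior identifies it. (A constant
  column *without* an intercept is informative and is not flagged; a
  two-point design with a constant regressor is a legitimate model.)
* **Ordering conventions.** Stacked output is deterministic: center blocks
  first (center ids in C-locale order), then cluster blocks, then the shared
  block, alphabetical within each block; copies are named
  `parameter[unit]`. Single-center ties break lexicographically.
* **Prior mapping under heterogeneity.** The combined prior places the
  parameter's marginal precision on each copy, independently across copies.
  A non-diagonal combined prior with cross-precision between a duplicated
  parameter and a shared one has no well-defined placement and is refused.
* **Serialization.** Summary and state files are schema-versioned JSON;
  matrices are written row-major with explicit dimensions and floats at 17
  significant digits, so payloads round-trip bit-exactly; unknown schema
  versions are rejected rather than coerced.
* **Seeds.** Every stochastic routine takes an explicit integer seed and
  restores the caller's RNG state; child seeds are derived arithmetically
  and kept below $2^{31}$.

## Scope and limitations

The federated estimates of covariate-distribution parameters (the marginal
law of $x$) are out of scope: only the outcome-model parameters
$(\beta, \zeta)$ are combined. Supported families are Gaussian-identity and
binomial-logit; the family object is an explicit interface (per-observation
log-density with derivatives), so adding e.g. Poisson-log is mechanical but
intentionally not part of the tested surface. There is no iterative
federated optimization, no random-effects/multilevel fitting, no survival
likelihood, no lasso-type prior (which would destroy the closed-form
combination), and no encryption layer on the payloads — the privacy claim
here is structural (summaries are $O(p^2)$ and contain no rows), not
cryptographic.

The quadratic surrogate is a large-sample device: with small local samples
or many center-specific parameters, local expansions are poor and the
federated estimate can drift from the pooled fit even when both are
computable. The diagnostics flag incompatible centers but do not select a
heterogeneity structure; that choice stays with the analyst.

## Problem sizes used in the validation suite

The packaged tests and the acceptance script run, by design, at desk scale:
50 random all-quadratic problems ($L \le 8$, $p \le 10$); the four-center
logistic MSE study at both size presets with $B = 100$; interval coverage
over 500 replicates of a $4 \times 500$ Gaussian study; the
precision-gain check over 20 seeds of a $4 \times 1000$ logistic study; 200
replicates of the leave-one-out diagnostic; a 25-center covariate-recovery
study with $B = 10^4$ draws; and the 25-hospital prediction experiment with
50 split repetitions. These sizes give Monte-Carlo error comfortably inside
the asserted bands while keeping the whole suite in the order of a minute.
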