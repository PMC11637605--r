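---
title: "Bayesian linear Ornstein-Uhlenbeck models for comparative hypotheses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian linear Ornstein-Uhlenbeck models for comparative hypotheses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

phylou fits linear models of continuous trait evolution on a phylogeny in
which the residuals — or the trait itself — follow an Ornstein-Uhlenbeck
(OU) process around a primary optimum. This vignette is the package's
account of the science: the models and their assumptions, the priors and
their units, the algebra behind the adaptive model, the numerical and design
choices, and what the validation machinery does and does not demonstrate.

## The model family

The response `y` evolves by the stochastic differential equation

    dy = -alpha (y - theta(t)) dt + sigma_y dB,

where `alpha` is the rate of adaptation toward the primary optimum `theta`
and `sigma_y dB` is white noise. Two reparameterizations make the
parameters biologically interpretable, and all priors are placed on these
scales:

* **phylogenetic half-life** `t_half = ln(2) / alpha`: the average time to
  evolve half the distance from the ancestral state to the optimum. Units:
  tree height (trees are rescaled to unit height for fitting; the fitted
  `t_half` is also reported back-transformed through the recorded
  `scale_factor`). `t_half >> 1` means the model collapses toward Brownian
  motion; `t_half ~ 0` means essentially instantaneous adaptation.
* **stationary variance** `v = sigma_y^2 / (2 alpha)`: the equilibrium
  among-species variance around a long-held optimum. Units: squared trait
  units.

The optimum is a linear function of predictors, giving the model menu:

* **multi-optima** (`kind = "multi_optima"`): `theta` takes one value per
  selective regime painted on the tree. The mean is `W theta`, where `W` is
  the Hansen regime-weight design matrix: row `i` holds the exponentially
  discounted fraction of tip `i`'s history spent in each regime (segment
  `(k, t_a, t_b)` contributes `exp(-alpha(T_i - t_b)) - exp(-alpha(T_i -
  t_a))` to regime `k`), with the residual root mass `exp(-alpha T_i)`
  assigned to the root's regime so rows sum to one. Assigning the root mass
  to the root regime (rather than estimating a separate ancestral state) is
  a deliberate simplification: the model menu contains no ancestral-optimum
  parameter, and the choice keeps `W` a proper weighting.
* **direct effect** (`"direct_effect"` / `"multi_optima_direct"`): changes
  in a continuous predictor produce an immediate correlated response,
  `mu = W theta + X beta`, with OU *residuals*. This is the natural model
  for allometric-constraint hypotheses. Note the model itself builds in no
  reason for residual phylogenetic correlation — a fitted `t_half > 0` is an
  empirical finding about the residuals, not a mechanism.
* **adaptive** (`"adaptive"` / `"multi_optima_adaptive"`): the optimum
  tracks a Brownian-motion predictor, `theta(t) = W theta + beta X(t)`,
  with `X` a BM with rate `sigma2_x`. Adaptation lags behind the moving
  optimum, so the observed ("evolutionary") regression of `y` on `x` is
  shallower than the optimal regression by the phylogenetic correction
  factor `rho(alpha T) = 1 - (1 - exp(-alpha T))/(alpha T)`; `rho -> 1`
  under instantaneous adaptation, `rho -> 0` toward Brownian motion.

Residual covariance between tips `i, j` with shared ancestry time `s_ij`
(from the root) and patristic separation `d_ij` is the Hansen OU form

    V_ij = v exp(-alpha d_ij) (1 - exp(-2 alpha s_ij)).

## Conditional moments of the adaptive model

The adaptive model needs the joint distribution of the response and the
predictor history. Solving the linear SDE along lineages that share ancestry
up to time `s` on an ultrametric tree of depth `T` gives, for the tip-level
working regression `y_i = W_i theta + beta rho(alpha T) x_i + r_i`
(the slope of `y` on `x` is exactly `beta rho(alpha T)`):

    Cov(r_i, r_j) = V_ij + b_i b_j sigma2_x kappa_ij
    kappa_ij = alpha^2 [J(T) - J(T - s_ij)] - 2 rho G(s_ij) + rho^2 s_ij
    alpha^2 J(t) = t - (3/2)(1 - e^{-2 alpha t})/alpha
                     + 2 (e^{-alpha t} - e^{-2 alpha t})/alpha
    G(s) = s - (e^{-alpha (T - s)} - e^{-alpha T})/alpha,

with `b_i` the slope of tip `i`'s regime when slopes vary. The limits pin
the algebra down: as `alpha -> infinity`, `kappa -> 0` and the model
reduces to the direct-effect model with independent residual variance `v`;
as `alpha -> 0` (holding `sigma_y^2` fixed) the whole model collapses to
Brownian motion. The test suite additionally verifies `kappa` against a
direct Euler-Maruyama simulation of the generative SDE on a three-tip tree,
so the covariance algebra is checked against the process itself rather than
against another formula. Because regime-specific slopes make the optimum
process piecewise in time, using the tip regime's slope in `kappa` is an
approximation for lineages that changed regimes; it is exact when slopes are
shared or regimes are tip-monophyletic.

The simulator draws responses from exactly this conditional law
(`Y | X ~ MVN(model_mean, model_covariance)`), which is also the likelihood
the sampler evaluates — the generative model and the inference model are the
same object, as a validation design requires. The predictor's BM rate
`sigma2_x` is estimated jointly by default under a weak lognormal prior
centered on the phylogenetic GLS plug-in estimate; `sigma2_x = "plugin"`
fixes it at that estimate instead.

## Regime paintings and Mk reconstruction

A painting assigns every node (root included) a regime; a regime assigned
to a node takes effect on the branches *below* that node, so a change
painted on an internal node splits the lineages through it at that node's
time, and the root's regime applies from time zero. One consequence worth
knowing: a tip's own label does not color any branch.

When only tip regimes are known, internal states can be reconstructed with
an Mk model (`mk_painting()`): ER, SYM and ARD rate structures are fitted by
maximizing the pruning-algorithm likelihood (multi-start box-constrained
L-BFGS-B on log rates in `[1e-8, 100]` per unit tree height — the ARD
surface is often multimodal), the structure is chosen by AIC, and internal
nodes take their marginal maximum-likelihood state (ties broken by lowest
state index, with a warning). The root state distribution is uniform; this
is an assumption, made explicit here because reasonable alternatives
(stationary frequencies, fitted root state) exist. Hard assignment of ML
states ignores reconstruction uncertainty; stochastic character mapping
would propagate it but is deliberately out of scope.

## Priors

Defaults follow explicit guidelines, constructed from the data by
`default_priors()` and always overridable:

* `t_half ~ logNormal` with the 10th percentile at 10% of tree height and
  the 90th at one tree height — spanning near-instantaneous adaptation to
  near-Brownian motion. The two-parameter solve is exact:
  `meanlog = (log 0.1 + log 1)/2`, `sdlog = (log 1 - log 0.1)/(2 z_0.9)`.
* `v ~ Exponential` with prior mean equal to the sample variance of the
  response (a uniform on `[0, 4 var(Y)]` and a half-Cauchy are available;
  the heavy-tailed options are preferable with few regimes).
* optima `theta ~ Normal(mean(Y), 1)`: centered on the observed mean with a
  spread of about two trait units either way.
* slopes `~ Normal(OLS slope, max(0.25, sd(Y)/sd(X)))`: instantaneous
  adaptation is akin to no phylogenetic effect, so the OLS slope anchors
  the prior; the scale is a package default meant to be checked by prior
  predictive simulation, not a universal constant.
* multilevel hyperpriors: hypermeans as above, scales `~ Exponential(1)`,
  and the 2x2 intercept/slope correlation `~ LKJ(4)` (mildly concentrated
  toward zero correlation).

`sim_study_priors()` returns the fixed example set used in the package's
simulation-study workflow (`t_half ~ logNormal(log 0.25, 0.25)`,
`v ~ Exponential(20)`, `theta_bar ~ N(0,1)`, `beta_bar ~ N(0, 0.25)`,
scales `~ Exponential(1)`, `Rho ~ LKJ(4)`). Note that this half-life prior
is tight around 0.25 tree heights: it is a workflow illustration; the
recovery validation uses the guideline prior above, which actually covers
the half-lives being recovered. Prior predictive checks
(`prior_predictive()`) should accompany any real analysis.

A documented caution, reproduced in the test machinery rather than fixed:
with a prior concentrated at an extreme of `t_half` (near zero or far above
tree height), the posterior follows the prior regardless of truth on small
trees. This is a property of OU models on phylogenies, not an artifact.

## Multilevel models and parameterization

With several regimes, optima (and slopes) can be drawn from a population
distribution: varying intercepts `theta_k ~ N(theta_bar, sigma_theta)`, or
joint varying effects `[theta_k, beta_k] ~ MVN([theta_bar, beta_bar],
diag(sigma) Rho diag(sigma))`. Partial pooling shares information across
regimes and helps unbalanced designs. Both a centered and a non-centered
parameterization are implemented; the non-centered form (hypermean +
scale x standardized deviate) is the default because hierarchical scale
parameters otherwise produce funnel geometry that the sampler diagnoses as
divergent transitions. The two parameterizations define the same posterior
(the package's tests verify density equality up to the exact Jacobian
`K log(sigma_theta sigma_beta sqrt(1 - rho^2))`).

## Measurement error

Response-side error with known standard errors is Gaussian-conjugate: the
latent true values marginalize exactly into diagonal inflation
`V + diag(se_y^2)`, so the package implements that single marginalized path
and tags it "latent (marginalized)" — it is mathematically identical to
sampling the latent responses, at none of the cost. Predictor-side error
cannot be marginalized (the predictor enters the mean multiplicatively with
parameters), so true predictor values are sampled as latent parameters,
reparameterized as `x_true = x_obs + se * u` with standardized `u` so the
sampler sees unit-scale coordinates. In the adaptive model the latent
predictors get their structural BM model; in the direct-effect model they
get a weak `N(x_obs, 10 se)` prior plus the observation model.

## Sampling and diagnostics

The sampler is a No-U-Turn sampler (recursive doubling with the slice
formulation, dual-averaging step-size adaptation targeting 0.8 acceptance,
and windowed diagonal mass-matrix estimation), with a self-contained RNG so
a seed fixes the draws exactly on a given platform. Defaults: 2 chains of
4000 iterations, half warmup — override freely. Divergent transitions are
counted and reported; more than 10% triggers a warning suggesting the
non-centered parameterization or a higher `adapt_delta`. Gradients of the
OU models are computed in compiled code: closed-form for every parameter
entering the covariance except the half-life (standard
`-tr(V^{-1} dV)/2 + u' dV u / 2` identities with `u = V^{-1} r`), cached
Cholesky central differences for mean-only parameters, and full central
differences for the half-life. The analytic and numerical paths are tested
against each other across all model configurations.

Convergence is summarized by split rank-normalized R-hat and a
Geyer-initial-monotone effective sample size; parameters with
`R-hat >= 1.1` or `n_eff < 100` are flagged in every summary. Those two
cutoffs are conventions, not guarantees; traceplots and reruns with more
iterations remain the fallback.

## Model comparison and predictive checks

Pointwise log-likelihoods are computed per posterior draw. Because the
responses are correlated through `V`, the default decomposition is the
leave-one-out *conditional* normal density (via the precision matrix); the
*marginal* decomposition (`N(mu_i, V_ii)`) is retained for speed and as a
cross-check, and its entries deliberately do not sum to the joint
log-likelihood when `V` has off-diagonal structure. Model comparison then
proceeds by:

* **PSIS-LOO** — importance ratios smoothed by a generalized-Pareto fit to
  the largest `min(0.2 S, 3 sqrt(S))` ratios, truncated at the raw maximum;
  the tail-shape diagnostic `k` is reported per observation (`<= 0.5` good,
  `<= 0.7` ok, `> 0.7` unreliable — small-sample leave-one-out on
  phylogenies often lands in the last bin, which is information, not
  failure).
* **WAIC** — `lppd - sum of pointwise posterior variances`.
* **bridge-sampling Bayes factors** — iterative bridge estimator with a
  moment-matched multivariate-normal proposal on the unconstrained scale
  (posterior draws split half for moment fitting, half for estimation;
  relative tolerance 1e-8), with an estimator SE from the standard
  relative-MSE approximation under an independence assumption — a lower
  bound for autocorrelated chains. Bayes factors with vague priors should
  be read conservatively.

All of these estimate out-of-sample predictive performance and are for
model *comparison*, not automatic selection. Prior and posterior predictive
checks (`prior_predictive()`, `posterior_predictive()`, `ppc_coverage()`)
replicate datasets through the generative simulator and report a pointwise
99% band-coverage statistic plus density overlays.

## The simulator and the validation design

`ou_sim_study()` reproduces the package's standard validation design: a
seeded pure-birth (Yule) tree scaled to unit height (a stand-in for an
empirical ultrametric phylogeny, which a code-only package cannot
redistribute — birth-death trees are more balanced than typical empirical
trees, which makes recovery slightly easier), four regimes painted on
random internal clades of 5-40 tips (root regime plus three, re-drawn until
every regime holds at least five tips), a BM predictor with `sigma2_x = 1`,
a multi-optima adaptive varying-effects response with `t_half = 0.1`,
`v = 0.01`, `theta = (1, 2, 3, 4)`, `beta = (0.75, 0.5, 0.35, 0.25)`, and
`N(0, 0.01^2)` measurement error added to both variables with 0.01 supplied
as the known SE. The predictor is mean-centered before it enters the
response mean, so recorded optima mean "optimum at the average predictor
value" — the same convention the fitting side uses for reporting
intercepts. Seeds derive from one master seed by a fixed counter scheme
(`derive_seed`), so adding a new random step never perturbs earlier
streams.

What passing these validations does *not* show: robustness to misspecified
paintings, non-Gaussian error, empirical tree shapes, within-species
sampling structure, or regimes that are not clade-shaped. The simulator
emulates the model's own assumptions by construction.

### Problem sizes used by the tests and the acceptance script

The validation machinery runs at desk scale, chosen as the package's own
test design: parameter-recovery studies use 30-tip trees with two regimes
and one predictor, 2 chains x 800 iterations, six replicates per half-life
setting (`t_half` in 0.1 / 0.25 / 0.75, `v = 0.01`), asserting >= 90%
coverage of truth by 95% compatibility intervals; the fixture workflow uses
40-tip versions of the simulation design with 2 chains x 400-1000
iterations; Monte-Carlo generative checks use 2e5 replicates on 4-tip
trees; the SDE cross-validation uses 4e4 Euler paths on a 3-tip tree.
Larger runs sharpen all of these but change nothing structural.

## Numerical choices

* Trees are rescaled to unit height before fitting; `scale_factor` carries
  the original height so half-lives are reported in both scalings.
* A relative jitter of `1e-10 v` is added to every covariance diagonal
  before factorization; a factorization failure after jitter is an error,
  never silent.
* Unconstrained transforms: log for `t_half`, `v`, scales and `sigma2_x`;
  `tanh` for the 2x2 correlation (with the LKJ normalizing constant
  included, so bridge-sampling marginals are comparable across models).
* `rho(x)` uses a second-order series below `x = 1e-5` to avoid
  cancellation; `rho(0) = 0` by continuity.
* Matrix orderings everywhere follow the tree's stored tip order, and all
  exported tables carry tip labels.
* Zero-length terminal branches are accepted; zero-length internal branches
  are collapsed to polytomies with a warning.
* Predictors are mean-centered internally; centering constants are stored
  so intercepts can be reported at the predictor mean or back-transformed.
* The evolutionary slope is reported deterministically as
  `beta * rho(alpha T)` per draw; a stochastic formulation (treating the
  evolutionary slope as a separate parameter) is out of scope.

## Known limitations

* Single response variable; no multivariate co-evolution of responses.
* One continuous predictor in the adaptive and by-regime-slope models.
* No time-varying or branch-specific `alpha`/`sigma_y`.
* The adaptive model requires an ultrametric tree (the `rho` expressions
  assume a common tip depth); multi-optima and direct-effect models accept
  non-ultrametric trees.
* Regime reconstruction by hard ML assignment understates painting
  uncertainty.
* Bridge-sampling SEs assume independent draws; with short chains they are
  optimistic.
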