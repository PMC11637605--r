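# phylou

Bayesian linear Ornstein-Uhlenbeck (OU) models for phylogenetic comparative
hypotheses.

Species are related by a phylogeny, so their trait values are not
independent observations — and the *pattern* of non-independence carries
information about adaptation. phylou is for comparative biologists who want
to test adaptive hypotheses on a time-calibrated tree: do optima differ
between selective regimes (niches) painted on the phylogeny? does a trait
track a continuously evolving predictor, and with how much lag? is an
allometric relationship consistent with immediate correlated response?

## The model

The response evolves as an Ornstein-Uhlenbeck process around a primary
optimum that is a linear function of predictors,

    dy = -alpha (y - theta(z, x)) dt + sigma_y dB,

parameterized by the **phylogenetic half-life** `t_half = ln(2)/alpha`
(average time to evolve half-way to a new optimum; the measure of
phylogenetic inertia) and the **stationary variance**
`v = sigma_y^2 / (2 alpha)` (equilibrium spread around a long-held
optimum). The implemented mean structures are

* multi-optima: `mu = W theta`, with `W` the Hansen regime-weight matrix of
  exponentially discounted time spent in each regime (rows sum to 1);
* direct effect: `mu = W theta + X beta` with OU residuals (allometric
  constraints);
* adaptive: the optimum tracks a Brownian predictor; the tip-level slope is
  `beta * rho(alpha T)` with `rho(x) = 1 - (1 - e^-x)/x` the phylogenetic
  correction factor, and the residual covariance gains predictor-history
  terms.

Residual covariance between tips is `V_ij = v e^{-alpha d_ij}
(1 - e^{-2 alpha s_ij})`. Multilevel (varying-intercept / varying-effect)
versions pool optima and slopes across regimes through hyperpriors with an
LKJ-correlated 2x2 covariance, in centered or non-centered
parameterizations. Measurement error is supported in the response
(marginalized exactly) and predictors (latent true values). Regimes can be
painted manually or reconstructed from tip states by Mk models (ER/SYM/ARD,
AIC selection). Inference is by a built-in No-U-Turn sampler with split
rank-normalized R-hat and effective-sample-size diagnostics; models are
compared by PSIS-LOO, WAIC and bridge-sampling Bayes factors, and checked
by prior/posterior predictive simulation. A generative simulator drives
validation end to end. See the methods vignette
(`vignettes/ou-models.Rmd`) for derivations and design decisions.

## Worked example

Simulate the standard validation design (four regimes on a 50-tip tree,
BM predictor, adaptive varying-slopes response, measurement error 0.01 on
both variables), then fit the matching model:

```r
library(phylou)
sim <- ou_sim_study(seed = 11, n_tips = 50)
print(sim)
#> phylou_sim: 50 tips, 4 regimes (tips per regime: 32/5/5/8)
#>   truth: t_half 0.1, v 0.01, theta (1, 2, 3, 4), beta (0.75, 0.5, 0.35, 0.25)

spec <- ou_model_spec("multi_optima_adaptive", multilevel = "none",
                      slopes = "by_regime")
fit <- ou_fit(sim$tree, sim$traits, response = "y", predictors = "x",
              painting = sim$painting, spec = spec,
              chains = 2, iter = 1000, warmup = 500, seed = 3, quiet = TRUE)
print(fit)
#> phylou_fit: multi_optima_adaptive (none, noncentered)
#>   50 species, 4 regimes; 2 chains x 1000 iterations (500 warmup)
#>   divergent transitions: 0; max R-hat 1.001; min n_eff 354

s <- summary(fit)
s[grepl("^(t_half$|v$|theta|beta)", s$parameter), ]
#>       parameter  mean ci_lower ci_upper     sd n_eff rhat flag
#> 1        t_half 0.123    0.040    0.267 0.0597   354    1
#> 2             v 0.014    0.004    0.031 0.0068  1000    1
#> 4      theta[1] 1.019    0.867    1.149 0.0726  1000    1
#> 5      theta[2] 2.102    1.696    2.753 0.2719   518    1
#> 6      theta[3] 2.937    2.431    3.816 0.3480   387    1
#> 7      theta[4] 4.021    3.765    4.561 0.1995   398    1
#> 8       beta[1] 0.743    0.638    0.932 0.0731   468    1
#> 9       beta[2] 0.540    0.250    0.982 0.1929   505    1
#> 10      beta[3] 0.560    0.207    1.116 0.2512   956    1
#> 11      beta[4] 0.257    0.110    0.452 0.0841   700    1
#> 12 beta_evol[1] 0.609    0.526    0.695 0.0430   985    1
#> ...
```

Every true value sits inside its 95% compatibility interval: the half-life
(truth 0.1), stationary variance (0.01), the four optima (1-4) and the four
optimal slopes (0.75/0.5/0.35/0.25). `beta_evol` rows are the evolutionary
slopes `beta * rho(alpha T)` — shallower than the optimal slopes because
adaptation lags. `t_half_original` (not shown) reports the half-life in the
tree's original time units via the recorded scale factor. Predictive
accuracy:

```r
psis_loo(fit)
#> PSIS-LOO: elpd_loo 22.74 (SE 4.49), p_loo 5.81
#> Pareto k: 46 good (<=0.5), 2 ok (<=0.7), 2 unreliable (>0.7)
#>   high-k observations: t10, t15
```

High Pareto-k species are ones whose removal shifts the posterior too much
for the importance-sampling approximation — typically long-isolated
lineages; they are named so you can inspect them.

There is also a command-line interface over the same functions
(`exec/phylou`, installed with the package):

    phylou simulate --seed 11 --out simdir
    phylou fit --tree simdir/tree.nwk --traits simdir/traits.csv \
        --config fit.yaml --out fitdir
    phylou compare fitdir1 fitdir2 --out cmpdir
    phylou check fitdir --mode posterior --out checkdir

Each run writes a `manifest.json` (config snapshot, input hashes, seeds,
version) from which seeded outputs reproduce bit-identically.

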