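# conjugate normal toy model: y_j ~ N(mu, s2) with known s2, mu ~ N(0, tau2)
conjugate_toy <- function(n = 10, s2 = 1, tau2 = 4, seed = 1, S = 2000,
                          mu_true = 0.5) {
  set.seed(seed)
  y <- rnorm(n, mu_true, sqrt(s2))
  post_var <- 1 / (n / s2 + 1 / tau2)
  post_mean <- post_var * sum(y) / s2
  mu_draws <- rnorm(S, post_mean, sqrt(post_var))
  pll <- vapply(seq_len(n),
                function(i) dnorm(y[i], mu_draws, sqrt(s2), log = TRUE),
                numeric(S))
  # exact LOO by n refits (posterior from n-1 observations -> predictive)
  exact <- vapply(seq_len(n), function(i) {
    v <- 1 / ((n - 1) / s2 + 1 / tau2)
    m <- v * sum(y[-i]) / s2
    dnorm(y[i], m, sqrt(v + s2), log = TRUE)
  }, 1.0)
  list(y = y, pll = pll, exact_loo = sum(exact), mu_draws = mu_draws)
}

test_that("constant log-likelihoods give elpd = sum and degenerate k", {
  pll <- matrix(rep(c(-1.2, -0.7, -2.1), each = 300), 300, 3)
  colnames(pll) <- letters[1:3]
  loo <- psis_loo(pll)
  expect_equal(loo$elpd_loo, sum(pll[1, ]))
  expect_true(all(loo$pareto_k <= 0))
  expect_lt(abs(loo$p_loo), 1e-8)
  w <- waic(pll)
  expect_equal(w$p_waic, 0)
  expect_equal(w$elpd_waic, sum(pll[1, ]))
})

test_that("PSIS-LOO matches exact refit LOO on the conjugate toy model", {
  toy <- conjugate_toy(n = 10, seed = 42, S = 4000)
  loo <- psis_loo(toy$pll)
  expect_lt(abs(loo$elpd_loo - toy$exact_loo), 2 * loo$se_elpd)
  expect_true(all(loo$pareto_k < 0.7))
  # WAIC agrees with PSIS-LOO within 2 SE on a well-specified model
  w <- waic(toy$pll)
  expect_lt(abs(w$elpd_waic - loo$elpd_loo), 2 * loo$se_elpd)
  expect_gt(loo$p_loo, 0)
})

test_that("the GPD tail-shape estimator recovers a known k", {
  k <- 0.5; sigma <- 1
  set.seed(9)
  u <- runif(4000)
  x <- sigma / k * ((1 - u)^(-k) - 1)       # GPD(k, sigma) draws
  fit <- phylou:::gpdfit(x)
  expect_lt(abs(fit$k - 0.5), 0.15)
  # light tail
  set.seed(10)
  e <- rexp(4000)
  expect_lt(abs(phylou:::gpdfit(e)$k), 0.2)
})

test_that("adding a pure-noise parameter increases p_waic", {
  wins <- 0L
  for (seed in 1:5) {
    toy <- conjugate_toy(n = 20, seed = seed, S = 2000)
    p1 <- waic(toy$pll)$p_waic
    # extra noise parameter: same data modeled with an extra fitted scale
    set.seed(seed + 100)
    noise <- exp(rnorm(nrow(toy$pll), 0, 0.2))
    pll2 <- vapply(seq_len(ncol(toy$pll)),
                   function(i) dnorm(toy$y[i], toy$mu_draws,
                                     sqrt(noise), log = TRUE),
                   numeric(nrow(toy$pll)))
    p2 <- waic(pll2)$p_waic
    if (p2 > p1) wins <- wins + 1L
  }
  expect_gte(wins, 4L)
})

test_that("elpd comparison: self-difference is exactly zero; ordering is sane", {
  toy <- conjugate_toy(n = 12, seed = 3, S = 1500)
  lA <- psis_loo(toy$pll)
  cmp <- compare_elpd(a = lA, b = lA)
  expect_equal(cmp$pairwise$elpd_diff, 0)
  expect_equal(cmp$pairwise$se_diff, 0)
  expect_false(cmp$pairwise$substantial)

  # the generating model wins against a biased one in most replicates
  wins <- 0L
  for (seed in 1:20) {
    toy <- conjugate_toy(n = 15, seed = seed, S = 600, mu_true = 0.5)
    pll_bad <- vapply(seq_along(toy$y),
                      function(i) dnorm(toy$y[i], toy$mu_draws + 1.5, 1,
                                        log = TRUE),
                      numeric(length(toy$mu_draws)))
    if (psis_loo(toy$pll)$elpd_loo >= psis_loo(pll_bad)$elpd_loo)
      wins <- wins + 1L
  }
  expect_gte(wins, 18L)
})

test_that("mismatched observation sets are rejected", {
  toy <- conjugate_toy(n = 8, seed = 5, S = 600)
  l1 <- psis_loo(toy$pll)
  l2 <- psis_loo(toy$pll[, 1:7])
  expect_error(compare_elpd(l1, l2), "different")
})

test_that("a contaminated observation gets the highest Pareto k", {
  hits <- 0L
  n_rep <- 10L
  for (seed in seq_len(n_rep)) {
    toy <- conjugate_toy(n = 15, seed = seed, S = 1500)
    y <- toy$y
    y[7] <- y[7] + 10                       # 10 residual SDs
    pll <- vapply(seq_along(y),
                  function(i) dnorm(y[i], toy$mu_draws, 1, log = TRUE),
                  numeric(length(toy$mu_draws)))
    k <- psis_loo(pll)$pareto_k
    if (which.max(k) == 7) hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})
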