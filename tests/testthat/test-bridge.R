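# conjugate normal-normal model with closed-form marginal likelihood:
# y_j ~ N(mu, s2) (s2 known), mu ~ N(m0, tau2)
# marginal: y ~ N(m0 1, s2 I + tau2 11')
conjugate_bridge_setup <- function(n = 25, s2 = 1, tau2 = 4, m0 = 0,
                                   seed = 1, S = 4000) {
  set.seed(seed)
  y <- rnorm(n, 1, sqrt(s2))
  post_var <- 1 / (n / s2 + 1 / tau2)
  post_mean <- post_var * (sum(y) / s2 + m0 / tau2)
  draws <- matrix(rnorm(S, post_mean, sqrt(post_var)), ncol = 1)
  log_target <- function(q) {
    mu <- q[1]
    sum(dnorm(y, mu, sqrt(s2), log = TRUE)) + dnorm(mu, m0, sqrt(tau2),
                                                    log = TRUE)
  }
  Vm <- s2 * diag(n) + tau2
  exact <- oracle_dmvnorm(y, rep(m0, n), Vm)
  list(draws = draws, log_target = log_target, exact = exact)
}

test_that("bridge sampling matches the closed-form conjugate marginal", {
  cb <- conjugate_bridge_setup(seed = 11, S = 4000)
  br <- bridge_log_marginal(cb$draws, log_target = cb$log_target, seed = 2)
  expect_true(br$converged)
  expect_lt(abs(br$log_marginal - cb$exact), 0.02)
  expect_true(is.finite(br$se))

  # invariance (within 3 estimator SEs) to doubling the draw count
  cb2 <- conjugate_bridge_setup(seed = 11, S = 8000)
  br2 <- bridge_log_marginal(cb2$draws, log_target = cb2$log_target, seed = 3)
  expect_lt(abs(br2$log_marginal - br$log_marginal),
            3 * sqrt(br$se^2 + br2$se^2) + 0.01)
})

test_that("Bayes factors are antisymmetric and near 1 for twin fits", {
  cb <- conjugate_bridge_setup(seed = 21, S = 3000)
  brA <- bridge_log_marginal(cb$draws, log_target = cb$log_target, seed = 5)
  # same model, different posterior draw stream and proposal seed
  set.seed(99)
  cbB <- cb
  cbB$draws <- cb$draws[sample(nrow(cb$draws)), , drop = FALSE]
  brB <- bridge_log_marginal(cbB$draws, log_target = cb$log_target, seed = 6)
  bf <- bayes_factor(brA, brB)
  expect_gt(bf$bf, 0.9)
  expect_lt(bf$bf, 1.1)
  bf_rev <- bayes_factor(brB, brA)
  expect_equal(bf$bf * bf_rev$bf, 1, tolerance = 1e-12)
})

test_that("degenerate inputs raise informative errors", {
  cb <- conjugate_bridge_setup(seed = 31, S = 1200)
  expect_error(bridge_log_marginal(cb$draws[1:500, , drop = FALSE],
                                   log_target = cb$log_target),
               "1000")
  expect_error(bridge_log_marginal(cb$draws,
                                   log_target = function(q) -Inf),
               "overlap")
})
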