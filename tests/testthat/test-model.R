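test_that("model mean obeys the centering and single-regime contracts", {
  tr <- scale_to_unit_height(three_tip_tree())
  p1 <- paint_regimes(tr, c(node_4 = "only"), "only")
  spec0 <- ou_model_spec("multi_optima")
  mu <- model_mean(tr, p1, spec0, list(t_half = 0.3, theta = 1.7))
  expect_equal(unname(mu), rep(1.7, 3))

  # direct effect with centered X: mean at X = 0 equals W theta
  spec1 <- ou_model_spec("multi_optima_direct")
  X <- c(A = -1, B = 0, C = 1)
  mu1 <- model_mean(tr, p1, spec1,
                    list(t_half = 0.3, theta = 2, beta = 0.5), X = X)
  expect_equal(unname(mu1), 2 + 0.5 * unname(X))
})

test_that("adaptive mean converges to the direct-effect mean as alpha grows", {
  tr <- scale_to_unit_height(three_tip_tree())
  p <- local({q <- two_regime_painting(three_tip_tree())
              q$tip_lineages <- phylou:::compute_tip_lineages(tr, q); q})
  X <- c(A = -0.8, B = 0.2, C = 1.1)
  pars <- list(t_half = log(2) / 60, theta = c(1, 2), beta = 0.5)
  mu_ad <- model_mean(tr, p, ou_model_spec("multi_optima_adaptive"), pars, X)
  mu_de <- model_mean(tr, p, ou_model_spec("multi_optima_direct"), pars, X)
  expect_lt(max(abs(mu_ad - mu_de)), 1e-6 + 0.5 * max(abs(X)) *
              (1 - rho_correction(60, 1)) * 2)
  expect_lt(max(abs(mu_ad - mu_de)), 0.02)
})

test_that("model covariance: multi-optima equals OU covariance; SEs inflate diagonal", {
  tr <- scale_to_unit_height(three_tip_tree())
  p1 <- paint_regimes(tr, c(node_4 = "only"), "only")
  spec <- ou_model_spec("multi_optima")
  pars <- list(t_half = 0.2, v = 0.05, theta = 0)
  V <- model_covariance(tr, p1, spec, pars)
  Vou <- ou_covariance(half_life_to_alpha(0.2), 0.05, tr)
  expect_lt(max(abs(V - Vou)), 1e-10 * 0.05 * 1.01)   # only the jitter differs
  Vme <- model_covariance(tr, p1, spec, pars, se_y = 0.01)
  expect_equal(unname(diag(Vme) - diag(V)), rep(1e-4, 3))
})

test_that("adaptive residual covariance matches SDE path simulation", {
  # Euler-Maruyama simulation of X (BM) and Y (OU tracking theta + b X) on
  # the 3-tip tree; empirical moments of the evolutionary-regression
  # residuals must match the model covariance within MC error
  tr <- scale_to_unit_height(three_tip_tree())
  p1 <- paint_regimes(tr, c(node_4 = "R1"), "R1")
  spec <- ou_model_spec("adaptive")
  th <- 0.25; al <- half_life_to_alpha(th); v <- 0.05; b <- 0.6; s2x <- 1
  pars <- list(t_half = th, v = v, theta = 0.3, beta = b, sigma2_x = s2x)
  nrep <- 40000; nstep <- 300; dt <- 1 / nstep
  sy <- sqrt(2 * al * v)
  set.seed(42)
  Xab <- Xc <- numeric(nrep)
  Yab <- Yc <- rep(pars$theta, nrep)
  Xa <- Xb <- Ya <- Yb <- NULL
  half <- nstep / 2
  for (i in 1:nstep) {
    Yc <- Yc - al * (Yc - pars$theta - b * Xc) * dt + sy * sqrt(dt) * rnorm(nrep)
    Xc <- Xc + sqrt(s2x * dt) * rnorm(nrep)
    if (i <= half) {
      Yab <- Yab - al * (Yab - pars$theta - b * Xab) * dt +
        sy * sqrt(dt) * rnorm(nrep)
      Xab <- Xab + sqrt(s2x * dt) * rnorm(nrep)
      if (i == half) { Xa <- Xab; Ya <- Yab; Xb <- Xab; Yb <- Yab }
    } else {
      Ya <- Ya - al * (Ya - pars$theta - b * Xa) * dt + sy * sqrt(dt) * rnorm(nrep)
      Xa <- Xa + sqrt(s2x * dt) * rnorm(nrep)
      Yb <- Yb - al * (Yb - pars$theta - b * Xb) * dt + sy * sqrt(dt) * rnorm(nrep)
      Xb <- Xb + sqrt(s2x * dt) * rnorm(nrep)
    }
  }
  X <- cbind(Xa, Xb, Xc); Y <- cbind(Ya, Yb, Yc)
  rho1 <- rho_correction(al, 1)
  # evolutionary regression slope = optimal slope * rho
  slope <- coef(lm(Y[, 1] ~ X[, 1]))[2]
  expect_lt(abs(slope - b * rho1), 0.02)
  r <- Y - pars$theta - b * rho1 * X
  emp <- cov(r)
  mod <- unname(model_covariance(tr, p1, spec, pars))
  # 3 MC SEs elementwise (cov-of-gaussians variance formula) + Euler bias
  se <- sqrt((outer(diag(mod), diag(mod)) + mod^2) / nrep)
  expect_true(all(abs(emp - mod) < 3 * se + 5e-4))
})

test_that("adaptive covariance limits: direct-effect at large alpha, BM at small", {
  tr <- scale_to_unit_height(three_tip_tree())
  p1 <- paint_regimes(tr, c(node_4 = "R1"), "R1")
  spec <- ou_model_spec("adaptive")
  v <- 0.04; b <- 0.5
  Vfast <- model_covariance(tr, p1, spec,
                            list(t_half = log(2) / 100, v = v, theta = 0,
                                 beta = b, sigma2_x = 1))
  expect_lt(max(abs(Vfast - diag(v, 3))), 0.02 * v + 1e-3)

  al0 <- 1e-6; s2y <- 0.3
  st <- shared_times(tr)
  Vslow <- model_covariance(tr, p1, spec,
                            list(alpha = al0, v = s2y / (2 * al0), theta = 0,
                                 beta = b, sigma2_x = 1))
  expect_lt(max(abs(Vslow - s2y * st$s)) / max(s2y * st$s), 2e-3)
})

test_that("OU log-likelihood reproduces the BM log-likelihood as alpha -> 0", {
  tr <- simulate_tree(10, seed = 31)
  st <- shared_times(tr)
  set.seed(32)
  s2y <- 0.8
  y <- as.numeric(t(chol(s2y * st$s + diag(1e-9, 10))) %*% rnorm(10))
  al0 <- 1e-6
  V_ou <- ou_covariance(al0, s2y / (2 * al0), st)
  ll_ou <- oracle_dmvnorm(y, rep(0, 10), V_ou)
  ll_bm <- oracle_dmvnorm(y, rep(0, 10), s2y * st$s + diag(1e-12, 10))
  expect_lt(abs(ll_ou - ll_bm), 1e-3)
})

test_that("the compiled log posterior equals a hand-assembled target", {
  tr <- scale_to_unit_height(three_tip_tree())
  p2 <- local({q <- two_regime_painting(three_tip_tree())
               q$tip_lineages <- phylou:::compute_tip_lineages(tr, q); q})
  spec <- ou_model_spec("multi_optima")
  y <- c(0.3, 0.9, -0.2)
  priors <- sim_study_priors()
  dat <- phylou:::build_model_data(tr, p2, spec, priors, y)
  xp <- phylou:::ou_model_build(dat)
  q <- c(log(0.3), log(0.02), 0.4, 1.2)      # log t_half, log v, theta1:2
  got <- phylou:::ou_model_logpost(xp, q)
  al <- log(2) / 0.3; v <- 0.02
  W <- regime_weights(al, tr, p2)
  V <- ou_covariance(al, v, tr) + diag(1e-10 * v, 3)
  want <- oracle_dmvnorm(y, as.numeric(W %*% c(0.4, 1.2)), V) +
    dnorm(log(0.3), log(0.25), 0.25, log = TRUE) +
    (log(20) - 20 * v + log(v)) +
    sum(dnorm(c(0.4, 1.2), 0, 1, log = TRUE))
  expect_equal(got, want, tolerance = 1e-10)

  # zero-regime-information sanity: K = 1 model's likelihood part responds
  # only through mu = theta
  p1 <- paint_regimes(tr, c(node_4 = "a"), "a")
  dat1 <- phylou:::build_model_data(tr, p1, spec, priors, y)
  xp1 <- phylou:::ou_model_build(dat1)
  q1 <- c(log(0.3), log(0.02), 0.4)
  expect_equal(phylou:::ou_model_logpost(xp1, q1),
               oracle_dmvnorm(y, rep(0.4, 3), V) +
                 dnorm(log(0.3), log(0.25), 0.25, log = TRUE) +
                 (log(20) - 20 * v + log(v)) + dnorm(0.4, 0, 1, log = TRUE),
               tolerance = 1e-10)
})

test_that("centered and non-centered targets differ only by the Jacobian", {
  sim <- ou_sim_study(seed = 21, n_tips = 20, min_tips = 3)
  priors <- sim_study_priors()
  Xc <- as.matrix(sim$traits$x) - mean(sim$traits$x)
  spec_c <- ou_model_spec("multi_optima_direct", "varying_effects", "centered")
  spec_n <- ou_model_spec("multi_optima_direct", "varying_effects", "noncentered")
  dat_c <- phylou:::build_model_data(sim$tree, sim$painting, spec_c, priors,
                                     sim$traits$y, NULL, Xc, NULL)
  dat_n <- phylou:::build_model_data(sim$tree, sim$painting, spec_n, priors,
                                     sim$traits$y, NULL, Xc, NULL)
  xc <- phylou:::ou_model_build(dat_c)
  xn <- phylou:::ou_model_build(dat_n)
  set.seed(5)
  for (rep in 1:5) {
    K <- 4
    tbar <- rnorm(1); st <- exp(rnorm(1, -1, 0.3))
    bbar <- rnorm(1, 0, 0.3); sb <- exp(rnorm(1, -1.5, 0.3))
    yr <- rnorm(1, 0, 0.5); r <- tanh(yr)
    zt <- rnorm(K); zb <- rnorm(K)
    theta <- tbar + st * zt
    beta <- bbar + sb * (r * zt + sqrt(1 - r^2) * zb)
    lt <- rnorm(1, log(0.25), 0.2); lv <- rnorm(1, -4, 0.5)
    q_n <- c(lt, lv, zt, tbar, log(st), zb, bbar, log(sb), yr)
    q_c <- c(lt, lv, theta, tbar, log(st), beta, bbar, log(sb), yr)
    diff <- phylou:::ou_model_logpost(xn, q_n) -
      phylou:::ou_model_logpost(xc, q_c)
    expect_equal(diff, K * log(st * sb * sqrt(1 - r^2)), tolerance = 1e-8)
  }
})
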