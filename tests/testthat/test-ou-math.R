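test_that("half-life / rate and variance reparameterizations are exact inverses", {
  expect_equal(half_life_to_alpha(log(2)), 1)
  expect_equal(half_life_to_alpha(0.25), 2.772589, tolerance = 1e-6)
  expect_equal(stationary_variance(2, 1), 1)
  expect_equal(sigma2_y_from_stationary(0.01, half_life_to_alpha(0.1)),
               0.13863, tolerance = 1e-4)
  set.seed(1)
  a <- exp(runif(100, -4, 4))
  expect_equal(half_life_to_alpha(alpha_to_half_life(a)), a)
  v <- exp(runif(100, -6, 2))
  expect_equal(stationary_variance(sigma2_y_from_stationary(v, a), a), v)
  expect_error(half_life_to_alpha(0), "> 0")
  expect_error(stationary_variance(-1, 1), "> 0")
})

test_that("rho correction matches scalar evaluations and limits", {
  expect_equal(rho_correction(half_life_to_alpha(0.25), 1), 0.66187,
               tolerance = 1e-5)
  expect_lt(abs(rho_correction(1000, 1) - 1), 0.0011)   # alpha t -> inf
  expect_lt(rho_correction(1e-8, 1), 1e-7)              # alpha t -> 0
  # monotone increasing on a 10^3-point grid
  x <- exp(seq(log(1e-4), log(100), length.out = 1000))
  r <- vapply(x, function(z) rho_correction(z, 1), 1.0)
  expect_true(all(diff(r) > 0))
  expect_true(all(r >= 0 & r < 1))
})

test_that("regime weights match hand evaluation and sum to one", {
  tr <- three_tip_tree()
  p1 <- paint_regimes(tr, c(node_4 = "only"), "only")
  W1 <- regime_weights(1.7, tr, p1)
  expect_equal(unname(W1[, 1]), rep(1, 3))

  p2 <- two_regime_painting(tr)
  W <- regime_weights(log(2), tr, p2)
  # hand evaluation: A's R1 weight = 1 - e^{-ln2 * 1} = 0.5
  expect_equal(unname(W["A", ]), c(0.5, 0.5), tolerance = 1e-12)
  expect_equal(unname(W["C", ]), c(1, 0), tolerance = 1e-12)

  # alpha -> infinity: terminal-segment regime takes all the weight
  Wf <- regime_weights(25 / 1, scale_to_unit_height(tr),
                       local({q <- p2; q$tip_lineages <- NULL
                              q$tip_lineages <- phylou:::compute_tip_lineages(
                                scale_to_unit_height(tr), q); q}))
  expect_lt(abs(Wf["A", "R1"] - 1), 1e-5)

  # row sums = 1 over 6 orders of magnitude of alpha, random paintings
  for (seed in c(3, 4)) {
    trr <- simulate_tree(20, seed = seed)
    pr <- random_clade_painting(trr, K = 3, size_range = c(4, 15),
                                min_tips = 3, seed = seed + 50)
    for (alpha in 10^seq(-3, 3)) {
      Wr <- regime_weights(alpha, trr, pr)
      expect_lt(max(abs(rowSums(Wr) - 1)), 1e-10)
      expect_true(all(Wr >= -1e-12 & Wr <= 1 + 1e-12))
    }
  }
})

test_that("OU covariance matches its closed form, limits, and is PD", {
  tr <- three_tip_tree()
  al <- half_life_to_alpha(0.1); v <- 0.01
  V <- ou_covariance(al, v, scale_to_unit_height(tr))
  expect_equal(unname(diag(V)), rep(v * (1 - exp(-2 * al)), 3))
  expect_equal(unname(V["A", "C"]), 0)    # s = 0: no shared history
  expect_equal(unname(diag(V))[1], 0.0099999, tolerance = 1e-5)

  # BM limit: V -> sigma2_y * s with sigma2_y = 2 alpha v held fixed
  al0 <- 1e-6; s2y <- 0.5; v0 <- s2y / (2 * al0)
  st <- shared_times(tr)
  V0 <- ou_covariance(al0, v0, st)
  expect_lt(max(abs(V0 - s2y * st$s) / max(s2y * st$s)), 1e-3)

  # symmetric PD for random (tree, alpha, v)
  set.seed(7)
  for (rep in 1:10) {
    trr <- simulate_tree(sample(5:25, 1), seed = 600 + rep)
    Vr <- ou_covariance(exp(runif(1, -2, 3)), exp(runif(1, -5, 1)),
                        shared_times(trr))
    expect_true(isSymmetric(unname(Vr)))
    expect_gt(min(eigen(Vr, symmetric = TRUE, only.values = TRUE)$values), 0)
  }
})
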