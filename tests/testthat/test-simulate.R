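test_that("tree simulation is seeded, ultrametric, unit height", {
  tr <- simulate_tree(2, seed = 1)
  expect_equal(n_tips(tr), 2L)
  expect_equal(unname(tip_depths(tr)), c(1, 1))        # cherry of height 1
  t1 <- simulate_tree(15, seed = 5)
  t2 <- simulate_tree(15, seed = 5)
  expect_identical(ape::write.tree(t1$phy), ape::write.tree(t2$phy))
  expect_true(is_ultrametric(t1))
  expect_error(simulate_tree(10), "seed")
})

test_that("Yule trees show the expected cherry statistics", {
  # E[cherries] = n/3, Var = 2n/45 under Yule (exact for n >= 4)
  n <- 20; B <- 300
  cherries <- vapply(seq_len(B), function(b) {
    tr <- simulate_tree(n, seed = 5000 + b)
    parents <- tr$phy$edge[tr$phy$edge[, 2] <= n, 1]
    sum(table(parents) == 2)
  }, 1L)
  se <- sqrt(2 * n / 45 / B)
  expect_lt(abs(mean(cherries) - n / 3), 3 * se)
})

test_that("BM simulation: zero variance, determinism, covariance oracle", {
  tr <- simulate_tree(4, seed = 9)
  expect_equal(unname(simulate_bm(tr, 0, seed = 1)), rep(0, 4))
  expect_identical(simulate_bm(tr, 1, seed = 2), simulate_bm(tr, 1, seed = 2))
  B <- 50000
  X <- vapply(seq_len(B), function(b) simulate_bm(tr, 1.3, seed = 10000 + b),
              numeric(4))
  emp <- cov(t(X))
  want <- 1.3 * shared_times(tr)$s
  se <- sqrt((outer(diag(want), diag(want)) + want^2) / B)
  expect_true(all(abs(emp - want) < 4 * se))
})

test_that("measurement error has the configured spread and reports its SE", {
  v <- rep(0, 1e5)
  expect_equal(add_measurement_error(v, 0, seed = 1)$observed, v)
  me <- add_measurement_error(v, 0.01, seed = 2)
  expect_true(sd(me$observed) > 0.0098 && sd(me$observed) < 0.0102)
  expect_equal(unname(me$reported_se), rep(0.01, 1e5))
  expect_identical(add_measurement_error(v[1:10], 0.01, seed = 3),
                   add_measurement_error(v[1:10], 0.01, seed = 3))
  expect_error(add_measurement_error(v[1:3], -1, seed = 1), ">= 0")
})

test_that("responses drawn at v = 0 collapse to the model mean", {
  tr <- simulate_tree(6, seed = 12)
  p <- phylou:::single_regime_painting(tr)
  spec <- ou_model_spec("multi_optima")
  y <- simulate_response(tr, p, spec, list(t_half = 0.2, v = 0, theta = 1.5),
                         seed = 1)
  expect_equal(unname(y), rep(1.5, 6), tolerance = 1e-5)
})

test_that("regime sample means approach the optima when adaptation is fast", {
  tr <- simulate_tree(40, seed = 13)
  p <- random_clade_painting(tr, K = 2, size_range = c(10, 30), seed = 14)
  spec <- ou_model_spec("multi_optima")
  pars <- list(t_half = 0.01, v = 0.01, theta = c(-1, 1))
  treg <- tip_regimes(tr, p)
  devs <- vapply(1:20, function(b) {
    y <- simulate_response(tr, p, spec, pars, seed = 800 + b)
    c(mean(y[treg == 1]) - (-1), mean(y[treg == 2]) - 1)
  }, numeric(2))
  expect_lt(max(abs(rowMeans(devs))), 3 * 0.1 / sqrt(20) + 0.05)
})

test_that("the simulation-study fixture carries the stated truth record", {
  sim <- ou_sim_study(seed = 8, n_tips = 40)
  expect_equal(sim$truth$theta, c(1, 2, 3, 4))
  expect_equal(sim$truth$beta, c(0.75, 0.5, 0.35, 0.25))
  expect_equal(sim$truth$t_half, 0.1)
  expect_equal(sim$truth$v, 0.01)
  expect_true(all(sim$truth$regime_tip_counts >= 5))
  expect_equal(nrow(sim$traits), 40)
  expect_true(all(c("species", "y", "y_se", "x", "x_se", "regime") %in%
                    names(sim$traits)))
  expect_equal(unname(sim$se_y), rep(0.01, 40))
  # pure function of the seed
  sim2 <- ou_sim_study(seed = 8, n_tips = 40)
  expect_identical(sim$Y_obs, sim2$Y_obs)
  expect_identical(ape::write.tree(sim$tree$phy), ape::write.tree(sim2$tree$phy))
})

test_that("simulation output files round-trip through the readers", {
  sim <- ou_sim_study(seed = 8, n_tips = 25, min_tips = 4)
  dir <- tempfile()
  paths <- write_sim(sim, dir)
  expect_true(all(file.exists(paths)))
  tr <- parse_newick(file = paths["tree"])
  expect_equal(sort(tip_labels(tr)), sort(tip_labels(sim$tree)))
  asg <- read_regime_assignments(paths["regimes"])
  p <- paint_regimes(tr, asg, sim$painting$regime_names)
  # node ids are renumbered on re-read; compare regimes by node label
  r_orig <- setNames(
    sim$painting$regime_names[sim$painting$node_regime],
    phylou:::node_labels(sim$tree))
  r_back <- setNames(p$regime_names[p$node_regime], phylou:::node_labels(tr))
  expect_equal(r_back[names(r_orig)], r_orig)
  truth <- jsonlite::read_json(paths["truth"], simplifyVector = TRUE)
  expect_equal(truth$theta, c(1, 2, 3, 4))
})
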