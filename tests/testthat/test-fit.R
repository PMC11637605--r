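test_that("a small end-to-end fit produces a sane summary and derived draws", {
  fit <- shared_small_fit()
  s <- summary(fit)
  expect_true(all(c("t_half", "v", "theta[1]", "theta[2]", "beta[1]",
                    "t_half_original") %in% s$parameter))
  expect_true(all(s$ci_lower <= s$ci_upper))
  # derived back-transform holds draw by draw (unit-height tree: factor 1)
  expect_equal(as.numeric(fit$draws[, , "t_half_original"]),
               as.numeric(fit$draws[, , "t_half"]) * fit$tree$scale_factor)
  expect_true(all(fit$draws[, , "t_half"] > 0))
  expect_true(all(fit$draws[, , "v"] > 0))
  # the fit recovers the generating optima direction (theta2 > theta1)
  expect_gt(mean(fit$draws[, , "theta[2]"]), mean(fit$draws[, , "theta[1]"]))
})

test_that("species mismatches are reported by name", {
  tr <- simulate_tree(6, seed = 21)
  traits <- data.frame(species = tip_labels(tr), y = rnorm(6))
  bad <- traits[-3, ]
  expect_error(ou_fit(tr, bad, "y", iter = 10, seed = 1),
               tip_labels(tr)[3])
  bad2 <- traits; bad2$species[2] <- "made_up"
  expect_error(ou_fit(tr, bad2, "y", iter = 10, seed = 1),
               tip_labels(tr)[2])
  expect_error(ou_fit(tr, traits, "z", iter = 10, seed = 1), "missing trait")
})

test_that("fits are reproducible bit-for-bit from the seed", {
  tr <- simulate_tree(10, seed = 30)
  p <- phylou:::single_regime_painting(tr)
  y <- simulate_response(tr, p, ou_model_spec("multi_optima"),
                         list(t_half = 0.2, v = 0.05, theta = 0), seed = 31)
  traits <- data.frame(species = tip_labels(tr), y = unname(y))
  f1 <- ou_fit(tr, traits, "y", chains = 2, iter = 300, warmup = 150,
               seed = 99, quiet = TRUE, pointwise = "none")
  f2 <- ou_fit(tr, traits, "y", chains = 2, iter = 300, warmup = 150,
               seed = 99, quiet = TRUE, pointwise = "none")
  expect_identical(f1$unc_draws, f2$unc_draws)
})

test_that("non-ultrametric trees are rejected for the adaptive model only", {
  tr <- parse_newick("((A:1,B:2):1,C:1.5);")
  set.seed(1)
  traits <- data.frame(species = c("A", "B", "C"), y = rnorm(3), x = rnorm(3))
  expect_error(ou_fit(tr, traits, "y", "x",
                      spec = ou_model_spec("adaptive"), iter = 10, seed = 1),
               "ultrametric")
  # direct effect accepts it
  f <- ou_fit(tr, traits, "y", "x", spec = ou_model_spec("direct_effect"),
              chains = 2, iter = 200, warmup = 100, seed = 2, quiet = TRUE,
              pointwise = "none")
  expect_s3_class(f, "phylou_fit")
})

test_that("tip-regime columns trigger Mk reconstruction with AIC selection", {
  sim <- ou_sim_study(seed = 44, n_tips = 25, min_tips = 4)
  msgs <- capture.output(
    fit <- ou_fit(sim$tree, sim$traits, "y", regimes = "regime",
                  spec = ou_model_spec("multi_optima"), chains = 2,
                  iter = 300, warmup = 150, seed = 5, pointwise = "none"),
    type = "message")
  expect_true(any(grepl("AIC", msgs)))
  expect_false(is.null(fit$mk_info))
  expect_equal(nrow(fit$mk_info$aic_table), 3L)
  expect_equal(fit$model_data$K, 4L)
})
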