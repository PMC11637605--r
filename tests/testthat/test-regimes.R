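test_that("a single-regime painting gives one full-lineage segment per tip", {
  tr <- three_tip_tree()
  p <- paint_regimes(tr, c(node_4 = "base"), "base")
  for (lin in p$tip_lineages) {
    expect_equal(nrow(lin), 1L)
    expect_equal(lin$t_start, 0)
  }
  expect_equal(p$tip_lineages$A$t_end, 2)
})

test_that("regime changes split lineages at the painted node's time", {
  tr <- three_tip_tree()
  p <- two_regime_painting(tr)      # root R0, clade (A,B) R1
  A <- p$tip_lineages$A
  expect_equal(A$regime, c(1, 2))
  expect_equal(A$t_start, c(0, 1))
  expect_equal(A$t_end, c(1, 2))
  C <- p$tip_lineages$C
  expect_equal(C$regime, 1)
  expect_equal(C$t_end, 2)
})

test_that("painting validation errors are informative", {
  tr <- three_tip_tree()
  expect_error(paint_regimes(tr, c(node_4 = "X"), regime_names = c("A", "B")),
               "not in")
  expect_error(paint_regimes(tr, c(node_5 = "R1"), "R1"), "root")
  expect_error(paint_regimes(tr, c(nosuch = "R1"), "R1"), "unknown node")
})

test_that("lineage segments tile [0, depth] for random paintings", {
  for (seed in c(5, 9)) {
    tr <- simulate_tree(25, seed = seed)
    p <- random_clade_painting(tr, K = 3, size_range = c(4, 18), min_tips = 3,
                               seed = seed + 100)
    root_reg <- p$node_regime[phylou:::root_node(tr)]
    for (i in seq_len(n_tips(tr))) {
      lin <- p$tip_lineages[[i]]
      expect_equal(lin$t_start[1], 0)
      expect_equal(lin$regime[1], root_reg)     # first segment = root regime
      expect_lt(abs(lin$t_end[nrow(lin)] - tip_depths(tr)[i]), 1e-12)
      if (nrow(lin) > 1)                        # contiguous, no gaps/overlaps
        expect_equal(lin$t_start[-1], lin$t_end[-nrow(lin)])
      expect_true(all(lin$regime <= length(p$regime_names)))
    }
  }
})

test_that("regime assignment files round-trip", {
  tr <- three_tip_tree()
  p <- two_regime_painting(tr)
  f <- tempfile(fileext = ".csv")
  write_regime_assignments(tr, p, f)
  asg <- read_regime_assignments(f)
  p2 <- paint_regimes(tr, asg, p$regime_names)
  expect_equal(p2$node_regime, p$node_regime)
})
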