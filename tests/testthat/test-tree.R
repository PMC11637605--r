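test_that("parse_newick handles minimal trees and records node times", {
  tr <- parse_newick("(A:1,B:1);")
  expect_equal(n_tips(tr), 2L)
  expect_equal(tr$height, 1)
  st <- shared_times(tr)
  expect_equal(unname(st$s["A", "B"]), 0)   # MRCA is the root at time 0

  tr3 <- three_tip_tree()
  expect_equal(unname(tip_depths(tr3)), c(2, 2, 2))
  st3 <- shared_times(tr3)
  expect_equal(unname(st3$s["A", "B"]), 1)
  expect_equal(unname(st3$s["A", "C"]), 0)
  expect_equal(unname(st3$d["A", "B"]), 2)
  expect_equal(unname(st3$d["A", "C"]), 4)
})

test_that("malformed Newick is rejected with a positioned error", {
  expect_error(parse_newick("((A:1,B:1):1,C:2"), "unclosed|malformed")
  expect_error(parse_newick("(A:1,B:1));"), "position")
})

test_that("trees without branch lengths or with duplicates are rejected", {
  phy <- ape::read.tree(text = "((A,B),C);")
  expect_error(as_phylou_tree(phy), "branch length")
  expect_error(parse_newick("(A:1,A:1);"), "duplicate")
})

test_that("scale_to_unit_height rescales, records the factor, and is idempotent", {
  tr <- parse_newick("((A:7,B:7):7,C:14);")   # height-14 tree
  expect_equal(tr$height, 14)
  s1 <- scale_to_unit_height(tr)
  expect_equal(s1$height, 1)
  expect_equal(s1$scale_factor, 14)
  expect_lt(abs(max(tip_depths(s1)) - 1), 1e-12)
  s2 <- scale_to_unit_height(s1)
  expect_equal(s2$phy$edge.length, s1$phy$edge.length)
  expect_equal(s2$scale_factor, 14)

  # topology and branch proportions preserved
  expect_equal(s1$phy$edge, tr$phy$edge)
  ratio <- tr$phy$edge.length / s1$phy$edge.length
  expect_lt(diff(range(ratio)), 1e-12 * 14)

  u <- scale_to_unit_height(parse_newick("(A:1,B:1);"))
  expect_equal(u$scale_factor, 1)
})

test_that("shared times match the path-walk oracle on random trees", {
  for (seed in c(11, 23, 37)) {
    tr <- simulate_tree(20, seed = seed)
    st <- shared_times(tr)
    or <- oracle_shared_times(tr)
    expect_lt(max(abs(st$s - or$s)), 1e-10)
    expect_lt(max(abs(st$d - or$d)), 1e-10)
    # d(i,j) = depth_i + depth_j - 2 s(i,j)
    dd <- outer(st$depths, st$depths, "+") - 2 * st$s
    expect_lt(max(abs(dd - st$d)), 1e-10)
    expect_true(isSymmetric(unname(st$s)))
    expect_equal(unname(diag(st$s)), unname(st$depths))
  }
})

test_that("zero-length internal branches collapse to polytomies with warning", {
  expect_warning(tr <- parse_newick("((A:1,B:1):0,C:1);"), "polytom")
  expect_equal(n_tips(tr), 3L)
  expect_equal(tr$phy$Nnode, 1L)
})
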