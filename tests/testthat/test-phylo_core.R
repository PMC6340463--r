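test_that("newick parsing handles minimal trees, supports and round-trips", {
  tr <- parse_newick("(A:1.0,B:1.0);")
  expect_equal(ape::Ntip(tr), 2)
  expect_equal(sort(tr$edge.length), c(1, 1))

  tr2 <- parse_newick("((A:1,B:1)95:2,C:3);")
  expect_true("95" %in% tr2$node.label)

  set.seed(42)
  rt <- ape::rtree(20)
  back <- parse_newick(write_newick(rt))
  expect_true(ape::all.equal.phylo(rt, back, use.edge.length = FALSE))
  expect_equal(sort(back$edge.length), sort(rt$edge.length),
               tolerance = 1e-9)
})

test_that("newick validation reports offsets, duplicates and missing lengths", {
  expect_error(parse_newick("((A,B),C));"), "offset")
  expect_error(parse_newick("((A:1,B:1):1,A:2);"), "duplicate")
  expect_warning(tr <- parse_newick("((A,B),C);"), "no branch lengths")
  expect_equal(tr$edge.length, rep(0, nrow(tr$edge)))
})

test_that("unit conversion applies the stated SNaQ/ms factors", {
  st <- species_tree_cu("(A:2,B:2);", unit_convention("SNAQ"))
  ms <- convert_branch_lengths(st, "MS")
  expect_equal(ms$tree$edge.length, c(0.5, 0.5))

  # organellar x4-then-/4: identity on lengths, exactly
  mito <- convert_branch_lengths(st, "MS", organelle = TRUE)
  expect_identical(mito$tree$edge.length, st$tree$edge.length)

  # invertibility
  back <- convert_branch_lengths(convert_branch_lengths(st, "MS"), "SNAQ")
  expect_equal(back$tree$edge.length, st$tree$edge.length)
  expect_error(convert_branch_lengths(st, "TIME"), "not convertible")
})

test_that("organelle SNAQ->MS conversion is the exact identity on random trees", {
  set.seed(7)
  for (i in 1:20) {
    tr <- ape::rtree(10)
    st <- species_tree_cu(tr, unit_convention("SNAQ"))
    out <- convert_branch_lengths(st, "MS", organelle = TRUE)
    expect_identical(out$tree$edge.length, tr$edge.length)
  }
})

test_that("exclusive-clade queries match rooted topology", {
  tr <- parse_newick("((A:1,B:1):1,C:2);")
  expect_true(is_exclusive_clade(tr, c("A", "B")))
  expect_false(is_exclusive_clade(tr, c("A", "C")))
  tr2 <- parse_newick("((A:1,B:1):1,(C:1,D:1):1);")
  expect_true(is_exclusive_clade(tr2, c("A", "B", "C", "D")))
  expect_error(is_exclusive_clade(tr, c("A", "Z")), "Z")
})

test_that("low-support collapse contracts the right branches and is idempotent", {
  tr <- parse_newick("((A:1,B:1)5:1,C:2);")
  star <- collapse_low_support(tr, 10)
  expect_equal(star$Nnode, 1)
  expect_setequal(star$tip.label, c("A", "B", "C"))

  hi <- parse_newick("((A:1,B:1)95:1,C:2);")
  expect_equal(collapse_low_support(hi, 10)$Nnode, hi$Nnode)
  expect_equal(collapse_low_support(hi, 0)$Nnode, hi$Nnode)

  # idempotence and tip-set preservation on a larger mixed tree
  big <- parse_newick("(((A:1,B:1)4:1,(C:1,D:1)80:1)9:1,(E:1,F:1)50:2);")
  once <- collapse_low_support(big, 10)
  twice <- collapse_low_support(once, 10)
  expect_setequal(once$tip.label, big$tip.label)
  expect_equal(twice$Nnode, once$Nnode)
  expect_error(collapse_low_support(big, -1), "non-negative")
})

test_that("root-to-tip variance is the population variance of tip depths", {
  expect_equal(root_to_tip_variance(parse_newick("((A:1,B:1):1,C:2);")), 0)
  expect_equal(root_to_tip_variance(parse_newick("(A:1,B:3);")), 1)
  un <- ape::unroot(ape::rtree(5))
  expect_error(root_to_tip_variance(un), "rooted")
})

test_that("time trees enforce ultrametricity within tolerance", {
  expect_s3_class(time_tree("((A:1,B:1):1,C:2);"), "time_tree")
  expect_error(time_tree("((A:1,B:2):1,C:2);"), "ultrametric")
  expect_s3_class(time_tree("((A:1,B:2):1,C:2);", ultrametric = FALSE),
                  "time_tree")
})
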