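test_that("an infinite stem branch forces monophyly of the pair", {
  st <- with_infinite_stem(triplet_tree(1), c("A", "B"))
  gts <- simulate_gene_trees(st, 1, 2000, seed = 1)
  mono <- vapply(gts, function(t) is_exclusive_clade(t, c("A_1", "B_1")),
                 logical(1))
  expect_true(all(mono))
})

test_that("triplet topology frequencies match the closed-form MSC probabilities", {
  n <- 30000
  st <- triplet_tree(1)
  sp <- radphylo:::.st_prep(st, 1)
  set.seed(2)
  cnt <- radphylo:::cpp_triplet_counts(sp$parent, sp$height, sp$order,
                                       sp$n_tip, sp$samples, 0L, 1L, 2L,
                                       as.integer(n))
  minor <- exp(-1) / 3
  for (k in 2:3)
    expect_lt(abs(cnt[k] / n - minor), 3 * prop_se(minor, n))
  expect_lt(abs(cnt[1] / n - (1 - 2 * minor)),
            3 * prop_se(1 - 2 * minor, n))
})

test_that("within-population pairwise coalescence time averages 0.5 ms units", {
  st <- species_tree_cu("(A:500,B:500);", unit_convention("MS"))
  gts <- simulate_gene_trees(st, lineage_sample(c(A = 2, B = 1)), 2000,
                             seed = 3)
  tt <- vapply(gts, function(t) {
    d <- ape::cophenetic.phylo(t)
    d["A_1", "A_2"] / 2
  }, numeric(1))
  # Exp(rate 2): mean 0.5, sd 0.5
  expect_lt(abs(mean(tt) - 0.5), 3 * 0.5 / sqrt(length(tt)))
})

test_that("gene trees conserve lineages and are reproducible under a seed", {
  st <- quartet_tree(0.5, 0.5)
  a <- simulate_gene_trees(st, 2, 5, seed = 11)
  b <- simulate_gene_trees(st, 2, 5, seed = 11)
  expect_identical(lapply(a, write_newick), lapply(b, write_newick))
  for (t in a) {
    expect_equal(ape::Ntip(t), 8)       # 4 species x 2 chromosomes
    expect_equal(t$Nnode, 7)            # binary rooted
    expect_true(all(t$edge.length >= 0))
  }
})

test_that("site patterns are always segregating and symmetric on a 2-species star", {
  st <- species_tree_cu("(A:3,B:3);", unit_convention("MS"))
  ps <- simulate_site_patterns(st, 1, 20000, seed = 4)
  der <- rowSums(ps$pattern)
  expect_true(all(der >= 1 & der <= ncol(ps$pattern) - 1))
  p_a <- mean(ps$pattern[, "A_1"] == 1 & ps$pattern[, "B_1"] == 0)
  expect_lt(abs(p_a - 0.5), 3 * prop_se(0.5, nrow(ps$pattern)))
})

test_that("mutation placement matches a brute-force enumeration oracle", {
  # P(pattern = {A,B} derived) equals the expected relative length of
  # branches subtending exactly {A_1, B_1}, estimated by enumerating
  # mutation placement over an independent sample of stored gene trees
  st <- triplet_tree(3)
  gts <- simulate_gene_trees(st, 1, 2000, seed = 5)
  frac_ab <- vapply(gts, function(t) {
    ntip <- ape::Ntip(t)
    lens <- t$edge.length
    share <- 0
    for (i in seq_len(nrow(t$edge))) {
      tips <- radphylo:::.tips_under(t, t$edge[i, 2])
      if (setequal(tips, c("A_1", "B_1"))) share <- share + lens[i]
    }
    share / sum(lens)
  }, numeric(1))
  expected <- mean(frac_ab)

  ps <- simulate_site_patterns(st, 1, 20000, seed = 6)
  obs <- mean(ps$pattern[, "A_1"] == 1 & ps$pattern[, "B_1"] == 1 &
                ps$pattern[, "C_1"] == 0)
  expect_lt(abs(obs - expected),
            3 * prop_se(expected, nrow(ps$pattern)) + 3 * sd(frac_ab) /
              sqrt(length(frac_ab)))
})

test_that("site-pattern simulation rejects infinite branch lengths", {
  st <- with_infinite_stem(triplet_tree(1), c("A", "B"))
  expect_error(simulate_site_patterns(st, 1, 10, seed = 1), "finite")
})

test_that("pattern matching honours groups, ignored taxa and polarity", {
  pat <- c(A_1 = 1L, A_2 = 1L, B_1 = 1L, B_2 = 1L,
           C_1 = 0L, C_2 = 0L, D_1 = 0L, D_2 = 0L)
  expect_true(pattern_matches_group(pat, c("A", "B")))
  expect_false(pattern_matches_group(pat, c("A", "C")))

  # flipped polarity accepted under "either", not under "derived-in-group"
  flip <- 1L - pat
  names(flip) <- names(pat)
  expect_true(pattern_matches_group(flip, c("A", "B")))
  expect_false(pattern_matches_group(flip, c("A", "B"),
                                     polarity = "derived-in-group"))

  # ignored-taxon relaxation
  pat2 <- c(A_1 = 1L, A_2 = 1L, B_1 = 1L, B_2 = 1L,
            C_1 = 1L, C_2 = 0L, D_1 = 0L, D_2 = 0L)
  expect_false(pattern_matches_group(pat2, c("A", "B")))
  expect_true(pattern_matches_group(pat2, c("A", "B"), ignored = "C"))

  expect_error(pattern_matches_group(pat, c("A", "B", "C", "D")),
               "undefined")
  expect_error(pattern_matches_group(pat, c("A", "B"), ignored = "A"),
               "disjoint")
})
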