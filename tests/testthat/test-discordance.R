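test_that("observed CFs count gene-tree quartet topologies", {
  t1 <- parse_newick("((A:1,B:1):1,(C:1,D:1):1);")
  cf <- observed_quartet_cfs(rep(c(t1), 4), c("A", "B", "C", "D"))
  expect_equal(cf$cf, c(1, 0, 0))
  expect_equal(cf$n, 4)

  t2 <- parse_newick("((A:1,C:1):1,(B:1,D:1):1);")
  t3 <- parse_newick("((A:1,D:1):1,(B:1,C:1):1);")
  cf2 <- observed_quartet_cfs(c(t1, t1, t2, t3), c("A", "B", "C", "D"))
  expect_equal(cf2$cf, c(0.5, 0.25, 0.25))
})

test_that("multiple tips per species average within genes first", {
  # the two choices of A tip give different quartet topologies
  tr <- parse_newick("((A_1:1,B_1:1):1,((A_2:1,C_1:1):1,D_1:2):1);")
  cf <- observed_quartet_cfs(c(tr), c("A", "B", "C", "D"))
  expect_equal(cf$cf, c(0.5, 0.5, 0))
  expect_equal(cf$n, 1)
})

test_that("uninformative gene-tree sets raise an error", {
  tr <- parse_newick("((A:1,B:1):1,C:2);")
  expect_error(observed_quartet_cfs(c(tr), c("A", "B", "C", "D")),
               "informative")
})

test_that("expected CFs follow the MSC closed form", {
  star <- species_tree_cu("(A:1,B:1,C:1,D:1);", unit_convention("COAL"))
  expect_equal(expected_quartet_cfs(star, c("A", "B", "C", "D"))$cf,
               rep(1 / 3, 3))

  deep <- quartet_tree(20, 20)
  expect_equal(expected_quartet_cfs(deep, c("A", "B", "C", "D"))$cf,
               c(1, 0, 0), tolerance = 1e-12)

  # t = ln 3 (single internal branch) -> (7/9, 1/9, 1/9)
  cat3 <- species_tree_cu(
    sprintf("((A:1,B:1):%.15g,(C:%.15g,D:%.15g):0.0);",
            log(3), 1 + log(3), 1 + log(3)),
    unit_convention("COAL"))
  expect_equal(expected_quartet_cfs(cat3, c("A", "B", "C", "D"))$cf,
               c(7 / 9, 1 / 9, 1 / 9), tolerance = 1e-12)

  # the internal path sums across both cherry stems
  bal <- quartet_tree(0.6, 0.4)
  expect_equal(expected_quartet_cfs(bal, c("A", "B", "C", "D"))$cf[2],
               exp(-1) / 3, tolerance = 1e-12)
  expect_error(expected_quartet_cfs(bal, c("A", "B", "C", "Z")), "Z")
})

test_that("observed CFs converge to expected CFs on simulated gene trees", {
  st <- quartet_tree(0.5, 0.5)
  n <- 3000
  gts <- simulate_gene_trees(st, 1, n, seed = 8)
  obs <- observed_quartet_cfs(gts, c("A", "B", "C", "D"))
  exp_cf <- expected_quartet_cfs(st, c("A", "B", "C", "D"))
  for (k in 1:3)
    expect_lt(abs(obs$cf[k] - exp_cf$cf[k]),
              3 * prop_se(exp_cf$cf[k], n))
})

test_that("the chi-squared CF fit reproduces a hand Pearson computation", {
  obs <- structure(list(species = LETTERS[1:4], cf = c(0.5, 0.25, 0.25),
                        n = 100), class = "quartet_cf")
  exp_cf <- structure(list(species = LETTERS[1:4], cf = rep(1 / 3, 3),
                           n = NA), class = "quartet_cf")
  fit <- cf_goodness_of_fit(obs, exp_cf)
  expect_equal(fit$statistic, 12.5, tolerance = 1e-6)
  expect_equal(fit$df, 2)
  expect_equal(fit$p_value, pchisq(12.5, 2, lower.tail = FALSE),
               tolerance = 1e-6)

  perfect <- cf_goodness_of_fit(obs, obs)
  expect_equal(perfect$statistic, 0)
  expect_equal(perfect$p_value, 1)

  expect_error(cf_goodness_of_fit(list(), list()), "empty")
})

test_that("CF goodness-of-fit is roughly calibrated under the MSC null", {
  st <- quartet_tree(0.4, 0.4)
  sp <- radphylo:::.st_prep(st, 1)
  exp_cf <- expected_quartet_cfs(st, c("A", "B", "C", "D"))
  n_genes <- 300
  set.seed(9)
  pvals <- vapply(1:200, function(r) {
    cnt <- radphylo:::cpp_quartet_counts(sp$parent, sp$height, sp$order,
                                         sp$n_tip, sp$samples,
                                         0L, 1L, 2L, 3L, as.integer(n_genes))
    obs <- structure(list(species = c("A", "B", "C", "D"),
                          cf = as.numeric(cnt) / n_genes, n = n_genes),
                     class = "quartet_cf")
    cf_goodness_of_fit(obs, exp_cf)$p_value
  }, numeric(1))
  rate <- mean(pvals < 0.05)
  expect_gte(rate, 0.01)
  expect_lte(rate, 0.10)
})

test_that("the clade-frequency test hits its analytic limits", {
  st <- with_infinite_stem(triplet_tree(1), c("A", "B"))
  res <- clade_frequency_test(st, c("A", "B"), n_reps = 5,
                              trees_per_rep = 500, seed = 10)
  expect_equal(res$p_value, 1.0)
  expect_equal(res$p_value, mean(res$freq), tolerance = 1e-12)

  star <- species_tree_cu("(A:1,B:1,C:1);", unit_convention("COAL"))
  res2 <- clade_frequency_test(star, c("A", "B"), n_reps = 20,
                               trees_per_rep = 2000, seed = 11)
  expect_lt(abs(res2$p_value - 1 / 3),
            3 * prop_se(1 / 3, 20 * 2000))
  expect_error(clade_frequency_test(star, c("A", "A")), "distinct")
})

test_that("clade frequency increases with the stem length", {
  p <- vapply(c(0.2, 1, 3), function(t)
    clade_frequency_test(triplet_tree(t), c("A", "B"), n_reps = 10,
                         trees_per_rep = 2000, seed = 12)$p_value,
    numeric(1))
  expect_true(all(diff(p) > 0))
})
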