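test_that("species consensus keeps only fixed unambiguous sites", {
  expect_equal(fix_species_sequence(c("ATG", "ATG")), "ATG")
  expect_equal(fix_species_sequence(c("ATG", "ATA")), "ATN")
  expect_equal(fix_species_sequence(c("ATG", "ATR")), "ATN")  # IUPAC het
  expect_equal(fix_species_sequence(c("ATG", "AT-")), "ATG")  # missing ignored
  expect_error(fix_species_sequence(c("ATG", "ATGA")), "length")
})

test_that("codon-site classification applies the state and missingness filters", {
  # K,K,K vs R,R,R,R,R,R: two states, retained
  kr <- c(rep("AAA", 3), rep("AGA", 6))
  names(kr) <- paste0("s", 1:9)
  cs <- classify_codon_site(kr)
  expect_equal(cs$n_states, 2)
  expect_true(cs$retained)

  # three amino-acid states -> filtered
  three <- c(AAA = "AAA", AGA = "AGA", GAA = "GAA", x = "AAA")
  expect_false(classify_codon_site(three)$retained)

  # >2 missing taxa -> filtered
  miss3 <- c(s1 = "AAA", s2 = "AAA", s3 = "NNN", s4 = "---", s5 = "ANN")
  cs3 <- classify_codon_site(miss3)
  expect_equal(sort(cs3$missing), c("s3", "s4", "s5"))
  expect_false(cs3$retained)

  expect_error(classify_codon_site(c(a = "AXA")), "invalid codon")
})

test_that("the scan finds the hand-built shared substitution and nothing else", {
  scan <- find_shared_substitutions(toy_alignment_set(), toy_group())
  expect_equal(scan$s_genes, 1)
  expect_equal(scan$s_sites, 1)
  expect_equal(scan$sites$gene, "gene2")
  expect_equal(scan$sites$codon, 2)
  expect_equal(scan$sites$focal_aa, "K")
  expect_equal(scan$sites$other_aa, "R")
  # gene2 codon 2 is the only variable amino-acid site (gene3's codon-2
  # variation is synonymous, Phe/Phe)
  expect_equal(scan$n_var, 1)

  expect_error(find_shared_substitutions(toy_alignment_set(),
                                         group_spec(LETTERS[1:5])),
               "contrast is undefined")

  # masking the qualifying codon in a required species removes the hit
  masked <- toy_alignment_set()
  substr(masked$gene2[["B"]], 4, 6) <- "NNN"
  expect_equal(find_shared_substitutions(masked, toy_group())$s_genes, 0)
})

test_that("the vectorized scan agrees with a per-column oracle on synthetic data", {
  cfg <- synth_config(n_genes = 25, codons_per_gene = 30, n_inject = 3,
                      miss_rate = 0.08, seed = 101)
  ds <- generate_dataset(cfg)
  grp <- group_spec(cfg$focal, cfg$required_present)
  fast <- find_shared_substitutions(ds$alignments, grp)
  slow <- naive_scan(ds$alignments, grp)
  expect_equal(fast$s_sites, slow$s_sites)
  expect_equal(fast$s_genes, slow$s_genes)
  expect_equal(fast$n_var, slow$n_var)
  expect_equal(sum(fast$missing_configs$count), fast$n_var)
  expect_equal(sum(fast$missing_configs$freq), 1, tolerance = 1e-12)
})

test_that("site filters commute (state filter before or after missingness)", {
  set.seed(13)
  aas <- c("AAA", "AGA", "GAA", "TTT", "NNN", "A-A")
  for (rep in 1:50) {
    col <- setNames(sample(aas, 8, replace = TRUE), paste0("s", 1:8))
    cs <- classify_codon_site(col)
    # order A: states first, then missingness; order B: reversed
    a <- cs$n_states <= 2 && length(cs$missing) <= 2
    b <- length(cs$missing) <= 2 && cs$n_states <= 2
    expect_identical(a, b)
    expect_identical(cs$retained, a)
  }
})

test_that("the ILS pattern probability matches a brute-force oracle", {
  # star tree, 4 species, group of two: enumerate mutation placement over
  # an independently simulated set of gene trees (diploid sampling).
  # Match: the branch subtends exactly both focal species' chromosomes (or
  # exactly the complement). Testable: the branch subtends a union of
  # complete species chromosome sets, neither empty nor everything. The
  # conditional pattern probability is E[match length]/E[testable length].
  star <- species_tree_cu("(A:2,B:2,C:2,D:2);", unit_convention("COAL"))
  grp <- group_spec(c("A", "B"))
  gts <- simulate_gene_trees(star, 2, 1500, seed = 14)
  species <- c("A", "B", "C", "D")
  target <- c("A_1", "A_2", "B_1", "B_2")
  shares <- vapply(gts, function(t) {
    m_len <- t_len <- 0
    for (i in seq_len(nrow(t$edge))) {
      tips <- radphylo:::.tips_under(t, t$edge[i, 2])
      sp_hit <- unique(sub("_[12]$", "", tips))
      complete <- setequal(tips, paste0(rep(sp_hit, each = 2), "_", 1:2))
      if (complete && length(sp_hit) < 4) {
        t_len <- t_len + t$edge.length[i]
        if (setequal(tips, target) ||
            setequal(tips, setdiff(t$tip.label, target)))
          m_len <- m_len + t$edge.length[i]
      }
    }
    c(m_len, t_len, sum(t$edge.length))
  }, numeric(3))
  oracle <- mean(shares[1, ] / shares[3, ]) / mean(shares[2, ] / shares[3, ])

  est <- estimate_ils_pattern_probability(star, grp, n_sims = 40000,
                                          seed = 15)
  expect_lt(abs(est$p_hat - oracle), 3 * est$se + 0.01)
})

test_that("pattern probability is Monte-Carlo consistent and missingness relaxes it", {
  st <- synth_config()$species_tree
  grp <- group_spec(c("sp1", "sp2", "sp3"), "sp4")
  small <- estimate_ils_pattern_probability(st, grp, n_sims = 10000, seed = 16)
  large <- estimate_ils_pattern_probability(st, grp, n_sims = 200000, seed = 17)
  expect_lt(abs(small$p_hat - large$p_hat), 3 * (small$se + large$se))

  # on the unconditional scale, ignoring taxa can only add matches
  cfgs <- data.frame(config = c(".", "sp7,sp8"), freq = c(0, 1))
  relaxed <- estimate_ils_pattern_probability(st, grp, cfgs, n_sims = 50000,
                                              condition_on_tested = FALSE,
                                              seed = 18)
  none <- estimate_ils_pattern_probability(st, grp, n_sims = 50000,
                                           condition_on_tested = FALSE,
                                           seed = 18)
  expect_gte(relaxed$p_hat + 1e-12, none$p_hat)

  bad <- data.frame(config = "sp4", freq = 1)
  expect_error(estimate_ils_pattern_probability(st, grp, bad), "required")
})

test_that("pattern probability decreases with the focal group's dispersal", {
  grp <- group_spec(c("A", "B"))
  sister <- species_tree_cu("((A:1,B:1):2,(C:2,D:2):1);",
                            unit_convention("COAL"))
  star <- species_tree_cu("(A:2,B:2,C:2,D:2);", unit_convention("COAL"))
  split <- species_tree_cu("((A:1,C:1):2,(B:2,D:2):1);",
                           unit_convention("COAL"))
  p <- vapply(list(sister, star, split), function(s)
    estimate_ils_pattern_probability(s, grp, n_sims = 30000, seed = 19)$p_hat,
    numeric(1))
  expect_true(p[1] > p[2] && p[2] > p[3])
})

test_that("PhyloGWAS P values: exact binomial tail and method labels", {
  expect_equal(phylogwas_pvalue(0, 100, 0.01)$p_value, 1)
  expect_equal(phylogwas_pvalue(0, 100, 0.01,
                                method = "dataset-grouping",
                                n_datasets = 50, seed = 1)$p_value, 1)

  # independent tail: sum of binomial point masses
  exact <- sum(dbinom(5:1000, 1000, 0.001))
  res <- phylogwas_pvalue(5, 1000, 0.001)
  expect_equal(res$p_value, exact, tolerance = 1e-12)
  expect_equal(res$p_value, 0.00366, tolerance = 0.01)  # Poisson-limit value
  expect_error(phylogwas_pvalue(5, 0, 0.001), "positive")
  expect_error(phylogwas_pvalue(50, 10, 0.001), "observed")
})

test_that("dataset-grouping and binomial-tail agree on a shared stream", {
  st <- synth_config()$species_tree
  grp <- group_spec(c("sp1", "sp2", "sp3"), "sp4")
  pp <- estimate_ils_pattern_probability(st, grp, n_sims = 200000, seed = 20,
                                         keep_indicators = TRUE)
  n_var <- 500
  observed <- max(2, ceiling(pp$p_hat * n_var) + 1)
  grp_p <- phylogwas_pvalue(observed, n_var, pp, method = "dataset-grouping")
  bin_p <- phylogwas_pvalue(observed, n_var, pp$p_hat)
  se <- sqrt(max(grp_p$p_value * (1 - grp_p$p_value), 1e-6) /
               grp_p$n_datasets)
  expect_lt(abs(grp_p$p_value - bin_p$p_value), 3 * se + 0.02)
})
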