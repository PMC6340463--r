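test_that("alignment filtering removes columns, then sequences, then alignments", {
  # column 3 is fully gapped; sequence s3 is mostly gaps afterwards
  aln <- c(s1 = "ACG-ACGT", s2 = "ACG-ACGT", s3 = "AC---G--",
           s4 = "ACG-ACGT", s5 = "ACG-ACGT")
  out <- filter_alignment(aln, min_col_occupancy = 0.10,
                          max_seq_gap_frac = 0.50, min_species = 4)
  expect_false(out$discard)
  expect_equal(unique(nchar(out$alignment)), 7)  # 1 column removed
  expect_false("s3" %in% names(out$alignment))   # 4/7 gaps > 50%
  expect_true(all(c("LOW_OCCUPANCY", "HIGH_GAP_FRACTION") %in%
                    out$log$reason))

  # dropping below 4 species discards the alignment (distinct from empty)
  small <- filter_alignment(aln[1:3], min_species = 4)
  expect_true(small$discard)
  expect_true("TOO_FEW_SPECIES" %in% small$log$reason)

  expect_error(filter_alignment(aln, min_col_occupancy = 1.5), "\\[0, 1\\]")

  # idempotence
  again <- filter_alignment(out$alignment, min_col_occupancy = 0.10,
                            max_seq_gap_frac = 0.50, min_species = 4)
  expect_identical(again$alignment, out$alignment)
  expect_equal(nrow(again$log), 0)
})

test_that("outgroup-monophyly filtering keeps clean and vacuous trees only", {
  good <- parse_newick("(((A_1:1,B_1:1):1,C_1:2):1,(out_1:1,out_2:1):2);")
  bad <- parse_newick("(((A_1:1,out_1:1):1,C_1:2):1,(B_1:1,out_2:1):2);")
  lone <- parse_newick("((A_1:1,B_1:1):1,out_1:2);")
  none <- parse_newick("((A_1:1,B_1:1):1,C_1:2);")
  gts <- gene_tree_set(list(good, bad, lone, none),
                       gene_id = c("g1", "g2", "g3", "g4"),
                       outgroup = "out")
  kept <- outgroup_monophyly_filter(gts)
  expect_setequal(kept$gene_id, c("g1", "g3", "g4"))
})

test_that("transcript selection keeps the best-supported tree per cluster", {
  t_hi <- parse_newick("(((A:1,B:1)95:1,(C:1,D:1)80:1)60:1,E:3);")
  t_lo <- parse_newick("(((A:1,B:1)95:1,(C:1,D:1)5:1)2:1,E:3);")
  t_zero <- parse_newick("(((A:1,B:1)3:1,(C:1,D:1)5:1)2:1,E:3);")
  gts <- gene_tree_set(list(t_hi, t_lo, t_zero),
                       gene_id = c("tr1", "tr2", "tr3"),
                       cluster_id = c("c1", "c1", "c2"))
  kept <- select_transcript_per_cluster(gts, 10)
  expect_equal(kept$gene_id, "tr1")   # c2's only tree has 0 good nodes

  # tie broken lexicographically by gene id
  tie <- gene_tree_set(list(t_hi, t_hi), gene_id = c("trB", "trA"),
                       cluster_id = c("c1", "c1"))
  expect_equal(select_transcript_per_cluster(tie, 10)$gene_id, "trA")
})

test_that("supermatrix concatenation tracks partitions and fills missing species", {
  alns <- list(g1 = c(A = "ACGACGACG", B = "ACGACGACG", C = "ACGACGACG"),
               g2 = c(A = "ACGTACGTACGT", B = "ACGTACGTACGT"))
  sm <- build_supermatrix(alns)
  expect_equal(unique(nchar(sm$matrix)), 21)
  expect_equal(sm$partitions$start, c(1, 10))
  expect_equal(sm$partitions$end, c(9, 21))
  expect_equal(substr(sm$matrix[["C"]], 10, 21), strrep("N", 12))
  expect_error(build_supermatrix(list()), "empty")
  expect_error(build_supermatrix(alns[c(1, 1)]), "duplicate")

  pf <- tempfile()
  write_partition_file(sm$partitions, pf)
  expect_equal(readLines(pf), c("DNA, g1 = 1-9", "DNA, g2 = 10-21"))
})

test_that("fourfold-degenerate extraction follows the standard-code degeneracy", {
  alns <- list(g1 = c(A = "GCAAAAGGA", B = "GCTAAAGGT", C = "GCGAAAGGC"))
  ff <- extract_fourfold_sites(alns)
  # codon 1 (GCx, Ala) and codon 3 (GGx, Gly) qualify; codon 2 (AAA, Lys,
  # 2-fold) does not
  expect_equal(ff$map$codon, c(1, 3))
  expect_equal(ff$sites[["A"]], "AA")
  expect_equal(ff$sites[["B"]], "TT")

  # a species missing at a column is ignored; others must all be 4-fold
  alns2 <- list(g1 = c(A = "GCA", B = "NNN", C = "GCG"))
  ff2 <- extract_fourfold_sites(alns2)
  expect_equal(ff2$map$codon, 1)
  expect_equal(ff2$sites[["B"]], "N")

  # translation invariance: any third-position base keeps the amino acid
  code <- Biostrings::GENETIC_CODE
  for (i in seq_len(nrow(ff$map))) {
    cdn <- substr(alns$g1, 3 * (ff$map$codon[i] - 1) + 1,
                  3 * ff$map$codon[i])
    for (cc in cdn) {
      aas <- code[paste0(substr(cc, 1, 2), c("A", "C", "G", "T"))]
      expect_equal(length(unique(aas)), 1)
    }
  }
})

test_that("prep filters are byte-stable across runs", {
  aln <- c(s1 = "ACG-ACGT", s2 = "ACG-ACGT", s3 = "AC---G--",
           s4 = "ACG-ACGT", s5 = "ACG-ACGT")
  a <- filter_alignment(aln)
  b <- filter_alignment(aln)
  expect_identical(serialize(a, NULL), serialize(b, NULL))
})
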