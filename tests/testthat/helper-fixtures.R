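# Shared fixtures, built in code.

# three-species tree with internal branch t on the 2*Ne (COAL) scale:
# minor rooted-triplet probability = exp(-t)/3 each
triplet_tree <- function(t) {
  species_tree_cu(sprintf("((A:1,B:1):%g,C:%g);", t, 1 + t),
                  unit_convention("COAL"))
}

# balanced quartet tree with stem lengths x and y above the two cherries
quartet_tree <- function(x, y) {
  h <- 1 + max(x, y)
  species_tree_cu(
    sprintf("((A:%g,B:%g):%g,(C:%g,D:%g):%g);", h - x, h - x, x,
            h - y, h - y, y),
    unit_convention("COAL"))
}

# set an internal branch (the one above the MRCA of `taxa`) to Inf
with_infinite_stem <- function(stcu, taxa) {
  tr <- stcu$tree
  node <- ape::getMRCA(tr, taxa)
  tr$edge.length[tr$edge[, 2] == node] <- Inf
  species_tree_cu(tr, stcu$convention)
}

# hand-built codon alignment set for the shared-substitution scan:
# 5 species A..E; gene2 codon 2 is a clean fixed difference separating the
# (non-monophyletic) focal pair {A, C} (Lys, AAA) from B, D, E (Arg, AGA).
toy_alignment_set <- function() {
  list(
    gene1 = c(A = "ATGGCA", B = "ATGGCA", C = "ATGGCA", D = "ATGGCA",
              E = "ATGGCA"),
    gene2 = c(A = "ATGAAA", B = "ATGAGA", C = "ATGAAA", D = "ATGAGA",
              E = "ATGAGA"),
    gene3 = c(A = "ATGTTT", B = "ATGTTC", C = "ATGTTT", D = "ATGTTT",
              E = "ATGTTT"))
}

toy_group <- function() group_spec(c("A", "C"), required_present = "B")

# naive per-column reimplementation of the scan, used as an oracle
naive_scan <- function(alignments, group) {
  universe <- unique(unlist(lapply(alignments, names)))
  s_sites <- 0L; s_genes <- character(0); n_var <- 0L
  for (g in names(alignments)) {
    cm <- radphylo:::.codon_matrix(alignments[[g]])
    for (j in seq_len(ncol(cm))) {
      cs <- classify_codon_site(cm[, j], max_missing = group$max_missing)
      if (!cs$retained) next
      if (any(group$required_present %in% cs$missing)) next
      if (cs$n_states < 2) next
      n_var <- n_var + 1L
      aa <- cs$aa
      fa <- unique(aa[group$focal])
      if (length(fa) != 1L || is.na(fa)) next
      others <- aa[setdiff(universe, c(group$focal, cs$missing))]
      others <- others[!is.na(others)]
      if (length(unique(others)) == 1L && unique(others) != fa) {
        s_sites <- s_sites + 1L
        s_genes <- union(s_genes, g)
      }
    }
  }
  list(s_sites = s_sites, s_genes = length(s_genes), n_var = n_var)
}

# Monte-Carlo standard error of a proportion
prop_se <- function(p, n) sqrt(p * (1 - p) / n)
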