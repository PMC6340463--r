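# Multispecies-coalescent simulation of gene trees and single-mutation site
# patterns over a species tree in coalescent units. The C++ core works on the
# ms time scale (units of 4*Ne generations; k lineages coalesce at rate
# k*(k-1)); all inputs are converted on entry.

# Branch lengths flagged infinite (forced monophyly) are replaced by this
# duration: the probability that two lineages fail to coalesce across it is
# exp(-1000), i.e. exactly 0 in double precision.
.INF_BRANCH_MS <- 500

#' Per-species chromosome sample sizes
#'
#' @param counts Named integer vector, one entry per species (>= 1 each), or
#'   a single unnamed integer to sample the same number from every species of
#'   a tree supplied at simulation time.
#' @return An object of class `lineage_sample`.
#' @export
lineage_sample <- function(counts) {
  if (length(counts) == 1L && is.null(names(counts))) {
    stopifnot(counts >= 1)
    return(structure(list(per_species = NULL, uniform = as.integer(counts)),
                     class = "lineage_sample"))
  }
  stopifnot(!is.null(names(counts)), all(counts >= 1))
  structure(list(per_species = setNames(as.integer(counts), names(counts)),
                 uniform = NULL),
            class = "lineage_sample")
}

# resolve a lineage_sample (or bare integer) against a species tree's tips
.resolve_sample <- function(sample, tips) {
  if (is.numeric(sample) && length(sample) == 1L) sample <- lineage_sample(sample)
  stopifnot(inherits(sample, "lineage_sample"))
  if (!is.null(sample$uniform))
    return(setNames(rep(sample$uniform, length(tips)), tips))
  missing <- setdiff(tips, names(sample$per_species))
  if (length(missing))
    stop("no chromosome count for species: ", paste(missing, collapse = ", "))
  sample$per_species[tips]
}

# species tree -> flat arrays for the C++ simulator (0-based ids, tips first)
.st_prep <- function(stcu, sample, allow_inf = TRUE) {
  stopifnot(inherits(stcu, "species_tree_cu"))
  ms <- convert_branch_lengths(stcu, unit_convention("MS"))
  tr <- ms$tree
  len <- tr$edge.length
  if (any(is.infinite(len))) {
    if (!allow_inf)
      stop("flagged-infinite branch lengths are not allowed here; ",
           "mutation placement needs finite branch lengths")
    len[is.infinite(len)] <- .INF_BRANCH_MS
  }
  ntip <- ape::Ntip(tr)
  nnode <- ntip + tr$Nnode
  parent <- rep(-1L, nnode)
  parent[tr$edge[, 2]] <- tr$edge[, 1] - 1L
  # node heights above the present: tips 0, internal = max child path
  # (divergence-time semantics, as in ms)
  height <- numeric(nnode)
  po <- ape::reorder.phylo(tr, "postorder")
  polen <- po$edge.length
  polen[is.infinite(polen)] <- .INF_BRANCH_MS
  for (i in seq_len(nrow(po$edge))) {
    p <- po$edge[i, 1]; ch <- po$edge[i, 2]
    height[p] <- max(height[p], height[ch] + polen[i])
  }
  order <- c(po$edge[, 2], ntip + 1L) - 1L  # children before parents, root last
  samples <- .resolve_sample(sample, tr$tip.label)
  chrom_species <- rep(tr$tip.label, samples)
  chrom_index <- unlist(lapply(samples, seq_len), use.names = FALSE)
  list(parent = parent, height = height, order = as.integer(order),
       n_tip = ntip, samples = as.integer(unname(samples)),
       tips = tr$tip.label,
       chrom = paste0(chrom_species, "_", chrom_index),
       chrom_species = chrom_species)
}

#' Simulate gene trees under the multispecies coalescent
#'
#' Draws rooted binary gene trees on the sampled chromosomes: within each
#' species-tree branch, lineages coalesce pairwise under the censored
#' Kingman coalescent at the rate implied by the branch's coalescent units;
#' lineages remaining at the root merge in the ancestral population. Gene
#' tree branch lengths are returned in ms units (4*Ne generations).
#' Chromosome tips are labelled `<species>_<index>`.
#'
#' @param species_tree A [species_tree_cu()].
#' @param sample A [lineage_sample()], or a single integer (chromosomes per
#'   species).
#' @param n_trees Number of gene trees.
#' @param seed Optional integer seed (`set.seed()` is called when supplied).
#' @return A `multiPhylo` of length `n_trees`.
#' @export
#' @examples
#' st <- species_tree_cu("((A:1,B:1):1,C:2);", unit_convention("COAL"))
#' gts <- simulate_gene_trees(st, 1, 10, seed = 1)
simulate_gene_trees <- function(species_tree, sample, n_trees, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (n_trees < 1) stop("n_trees must be >= 1")
  sp <- .st_prep(species_tree, sample)
  if (sum(sp$samples) < 2) stop("at least two chromosomes must be sampled")
  raw <- cpp_sim_trees(sp$parent, sp$height, sp$order, sp$n_tip, sp$samples,
                       as.integer(n_trees))
  out <- lapply(raw, .merges_to_phylo, chrom = sp$chrom)
  class(out) <- "multiPhylo"
  out
}

#' @rdname simulate_gene_trees
#' @export
simulate_gene_tree <- function(species_tree, sample, seed = NULL) {
  simulate_gene_trees(species_tree, sample, 1L, seed = seed)[[1]]
}

# merge lists (0-based gene-node ids, tips 0..n-1) -> ape phylo
.merges_to_phylo <- function(m, chrom) {
  n <- length(chrom)
  nmerge <- n - 1L
  # ape ids: tips 1..n; gene internal id i in n..(2n-2), created last = root,
  # mapped so the root becomes n+1
  ape_id <- function(g) ifelse(g < n, g + 1L, (2L * n - 2L - g) + n + 1L)
  times <- c(rep(0, n), m$time)
  edge <- matrix(0L, nrow = 2L * nmerge, ncol = 2L)
  elen <- numeric(2L * nmerge)
  row <- 1L
  for (i in seq_len(nmerge)) {
    g <- n - 1L + i                       # 0-based merge node id
    for (ch in c(m$left[i], m$right[i])) {
      edge[row, ] <- c(ape_id(g), ape_id(ch))
      elen[row] <- m$time[i] - times[ch + 1L]
      row <- row + 1L
    }
  }
  structure(list(edge = edge, edge.length = elen, tip.label = chrom,
                 Nnode = nmerge),
            class = "phylo")
}

#' Simulate single-mutation site patterns under the MSC
#'
#' For each replicate, a gene tree is simulated and exactly one mutation is
#' placed on a branch chosen with probability proportional to branch length
#' (the infinite-sites, single-segregating-site model, equivalent to ms with
#' `-s 1`); the returned binary pattern marks the chromosomes inheriting the
#' derived state. Every pattern has at least one derived and one ancestral
#' chromosome. Requires finite species-tree branch lengths.
#'
#' @inheritParams simulate_gene_trees
#' @param n_sims Number of site patterns.
#' @return An object of class `site_pattern_set`: a list with `pattern`
#'   (0/1 integer matrix, `n_sims` rows, one column per chromosome),
#'   `chrom`, `chrom_species` and `branch` (diagnostic gene-tree branch
#'   index per pattern).
#' @export
simulate_site_patterns <- function(species_tree, sample, n_sims, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sp <- .st_prep(species_tree, sample, allow_inf = FALSE)
  if (sum(sp$samples) < 2) stop("at least two chromosomes must be sampled")
  raw <- cpp_site_patterns(sp$parent, sp$height, sp$order, sp$n_tip,
                           sp$samples, as.integer(n_sims), TRUE)
  pat <- raw$pattern
  colnames(pat) <- sp$chrom
  structure(list(pattern = pat, chrom = sp$chrom,
                 chrom_species = sp$chrom_species, branch = raw$branch),
            class = "site_pattern_set")
}

#' @rdname simulate_site_patterns
#' @export
simulate_site_pattern <- function(species_tree, sample, seed = NULL) {
  s <- simulate_site_patterns(species_tree, sample, 1L, seed = seed)
  structure(list(state = setNames(as.integer(s$pattern[1, ]), s$chrom),
                 chrom = s$chrom, chrom_species = s$chrom_species,
                 branch = s$branch[1]),
            class = "site_pattern")
}

#' Write site patterns as a 0/1 TSV
#'
#' @param patterns A `site_pattern_set`.
#' @param file Output path; columns are chromosome identifiers.
#' @export
write_site_patterns <- function(patterns, file) {
  stopifnot(inherits(patterns, "site_pattern_set"))
  write.table(patterns$pattern, file, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(file)
}

#' Does a site pattern match a group contrast?
#'
#' Restricting attention to chromosomes of non-ignored species, the pattern
#' matches iff all group chromosomes carry one state and all non-group
#' chromosomes carry the other. With `polarity = "either"` (the default,
#' since amino-acid fixed differences are unpolarized) both assignments of
#' derived/ancestral to the group are accepted; with `"derived-in-group"`
#' the group must carry the derived state.
#'
#' @param pattern A `site_pattern`, or a named 0/1 vector over chromosomes
#'   named `<species>_<index>`.
#' @param group Character vector of focal species.
#' @param required_present Species that may never be ignored (the focal
#'   species are always required).
#' @param ignored Species whose chromosomes are dropped before matching.
#' @param polarity `"either"` or `"derived-in-group"`.
#' @return Logical scalar.
#' @export
pattern_matches_group <- function(pattern, group, required_present = character(),
                                  ignored = character(),
                                  polarity = c("either", "derived-in-group")) {
  polarity <- match.arg(polarity)
  if (inherits(pattern, "site_pattern")) {
    state <- pattern$state
    species <- pattern$chrom_species
  } else {
    state <- pattern
    if (is.null(names(state))) stop("pattern vector must be named")
    species <- sub("_[^_]+$", "", names(state))
  }
  if (length(intersect(group, ignored)))
    stop("group and ignored species sets must be disjoint")
  if (length(intersect(required_present, ignored)))
    stop("required-present species cannot be ignored")
  keep <- !(species %in% ignored)
  sp_kept <- unique(species[keep])
  if (all(sp_kept %in% group))
    stop("group covers all non-ignored species; the contrast is undefined")
  in_group <- species[keep] %in% group
  s <- state[keep]
  match_derived <- all(s[in_group] == 1L) && all(s[!in_group] == 0L)
  if (polarity == "derived-in-group") return(match_derived)
  match_derived || (all(s[in_group] == 0L) && all(s[!in_group] == 1L))
}
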