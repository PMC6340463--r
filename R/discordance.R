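# ILS-null discordance analyses: the clade-frequency test for organellar
# introgression, and observed vs expected quartet concordance factors with a
# chi-squared goodness-of-fit.

#' Clade-frequency test for introgression against the ILS null
#'
#' Simulates gene trees under the MSC over the species tree and records, per
#' replicate, the fraction in which the two focal species form an exclusive
#' clade; the P value is the mean fraction across replicates. A small P says
#' that the observed clustering (e.g. of two species in a mitochondrial
#' tree) is unlikely under ILS alone, pointing to introgression. With
#' `organelle = TRUE` the branch lengths receive the organellar Ne
#' rescaling (x4 for mitochondria) before conversion to the simulator's ms
#' scale — for a SNAQ-unit input tree the two factors cancel exactly — and
#' one chromosome per species is simulated.
#'
#' @param species_tree A [species_tree_cu()].
#' @param pair Character vector of two distinct species.
#' @param organelle Simulate an organellar locus (quarter-Ne rescaling)?
#' @param n_reps Number of replicates (default 100).
#' @param trees_per_rep Gene trees per replicate (default 100000).
#' @param seed Optional integer seed.
#' @return An object of class `clade_frequency_result` with fields `pair`,
#'   `freq` (per-replicate clade frequencies), `p_value`, `n_reps`,
#'   `trees_per_rep`, `organelle`.
#' @export
clade_frequency_test <- function(species_tree, pair, organelle = FALSE,
                                 n_reps = 100, trees_per_rep = 100000,
                                 seed = NULL) {
  stopifnot(inherits(species_tree, "species_tree_cu"))
  pair <- as.character(pair)
  if (length(pair) != 2L || pair[1] == pair[2])
    stop("pair must be two distinct species")
  missing <- setdiff(pair, species_tree$tree$tip.label)
  if (length(missing))
    stop("species not in tree: ", paste(missing, collapse = ", "))
  if (!is.null(seed)) set.seed(seed)
  st <- if (organelle)
    convert_branch_lengths(species_tree, species_tree$convention,
                           organelle = TRUE)
  else species_tree
  sp <- .st_prep(st, 1L)
  target <- which(sp$tips %in% pair) - 1L  # one chromosome per species
  freq <- vapply(seq_len(n_reps), function(r) {
    cpp_clade_count(sp$parent, sp$height, sp$order, sp$n_tip, sp$samples,
                    as.integer(target), as.integer(trees_per_rep)) /
      trees_per_rep
  }, numeric(1))
  structure(list(pair = pair, freq = freq, p_value = mean(freq),
                 n_reps = n_reps, trees_per_rep = trees_per_rep,
                 organelle = organelle),
            class = "clade_frequency_result")
}

#' @export
print.clade_frequency_result <- function(x, ...) {
  cat("Clade-frequency ILS test:", paste(x$pair, collapse = " + "), "\n")
  cat(sprintf("  P = %.4g  (%d replicates x %d gene trees%s)\n",
              x$p_value, x$n_reps, x$trees_per_rep,
              if (x$organelle) ", organellar scaling" else ""))
  invisible(x)
}

# canonical quartet topology index for a sorted species quartet s1<s2<s3<s4:
# 1 = s1s2|s3s4, 2 = s1s3|s2s4, 3 = s1s4|s2s3.  `pair` is a 2-subset of 1:4
# (positions in the sorted quartet).
.pair_to_topology <- function(pair) {
  if (setequal(pair, c(1, 2)) || setequal(pair, c(3, 4))) return(1L)
  if (setequal(pair, c(1, 3)) || setequal(pair, c(2, 4))) return(2L)
  3L
}

# topology index of the unrooted quartet induced by four tips of `tree`
# (tips4 ordered to match sorted species); NA when unresolved (polytomy)
.quartet_topology <- function(tree, tips4, parts = NULL) {
  idx <- match(tips4, tree$tip.label)
  if (is.null(parts)) parts <- ape::prop.part(tree)
  for (cl in parts) {
    r <- which(idx %in% cl)
    if (length(r) == 2L) return(.pair_to_topology(r))
  }
  NA_integer_
}

#' Observed quartet concordance factors from gene trees
#'
#' For each gene tree, every combination of one tip per quartet species is
#' restricted to its induced unrooted quartet topology; per-gene topology
#' proportions (over resolved combinations) are then averaged with equal
#' weight across genes. This mirrors the two-step tip-based-then-mapped CF
#' computation used with phylogenetic-network inputs.
#'
#' @param gene_trees A `multiPhylo` (or list of `phylo`).
#' @param quartet Character vector of four distinct species.
#' @param tip_map Named character vector mapping tip labels to species;
#'   defaults to tips being species labels. Tips created by
#'   [simulate_gene_trees()] (named `<species>_<index>`) are recognised
#'   automatically.
#' @return An object of class `quartet_cf`: list with `species` (sorted),
#'   `cf` (three concordance factors in canonical topology order
#'   s1s2|s3s4, s1s3|s2s4, s1s4|s2s3), and `n` (informative gene trees).
#' @export
observed_quartet_cfs <- function(gene_trees, quartet, tip_map = NULL) {
  if (inherits(gene_trees, "phylo")) gene_trees <- c(gene_trees)
  quartet <- sort(unique(as.character(quartet)))
  if (length(quartet) != 4L) stop("quartet must contain four distinct species")
  per_gene <- matrix(NA_real_, nrow = length(gene_trees), ncol = 3)
  for (g in seq_along(gene_trees)) {
    tr <- gene_trees[[g]]
    map <- .resolve_tip_map(tr$tip.label, tip_map)
    tips_by_sp <- lapply(quartet, function(s) tr$tip.label[map == s])
    if (any(vapply(tips_by_sp, length, integer(1)) == 0L)) next
    combos <- expand.grid(tips_by_sp, stringsAsFactors = FALSE)
    parts <- ape::prop.part(tr)
    counts <- c(0, 0, 0)
    for (i in seq_len(nrow(combos))) {
      top <- .quartet_topology(tr, as.character(combos[i, ]), parts)
      if (!is.na(top)) counts[top] <- counts[top] + 1
    }
    if (sum(counts) > 0) per_gene[g, ] <- counts / sum(counts)
  }
  informative <- !is.na(per_gene[, 1])
  if (!any(informative))
    stop("no gene tree is informative for quartet ",
         paste(quartet, collapse = ", "))
  cf <- colMeans(per_gene[informative, , drop = FALSE])
  structure(list(species = quartet, cf = cf, n = sum(informative)),
            class = "quartet_cf")
}

.resolve_tip_map <- function(tips, tip_map) {
  if (!is.null(tip_map)) {
    miss <- setdiff(tips, names(tip_map))
    if (length(miss))
      stop("tip(s) missing from tip_map: ", paste(miss, collapse = ", "))
    return(unname(tip_map[tips]))
  }
  # default: "<species>_<index>" tips or species-labelled tips
  ifelse(grepl("_[^_]+$", tips), sub("_[^_]+$", "", tips), tips)
}

#' Expected quartet concordance factors under the MSC
#'
#' With `t` the internal branch length of the species quartet (the species
#' tree pruned to the four taxa, unrooted), measured in coalescent units on
#' the 2*Ne-generation scale, the species-tree (major) topology has expected
#' CF `1 - (2/3) exp(-t)` and each minor topology `(1/3) exp(-t)`. A star
#' quartet gives (1/3, 1/3, 1/3).
#'
#' @param species_tree A [species_tree_cu()].
#' @param quartet Character vector of four distinct species.
#' @return A `quartet_cf` (with `n = NA`); CFs in canonical topology order.
#' @export
expected_quartet_cfs <- function(species_tree, quartet) {
  stopifnot(inherits(species_tree, "species_tree_cu"))
  quartet <- sort(unique(as.character(quartet)))
  if (length(quartet) != 4L) stop("quartet must contain four distinct species")
  missing <- setdiff(quartet, species_tree$tree$tip.label)
  if (length(missing))
    stop("species not in tree: ", paste(missing, collapse = ", "))
  coal <- convert_branch_lengths(species_tree, unit_convention("COAL"))
  sub <- ape::keep.tip(coal$tree, quartet)
  usub <- ape::unroot(sub)
  ntip <- ape::Ntip(usub)
  internal <- usub$edge[, 1] > ntip & usub$edge[, 2] > ntip
  t_int <- sum(usub$edge.length[internal])
  major <- if (t_int > 0) .quartet_topology(sub, quartet) else NA_integer_
  minor <- exp(-t_int) / 3
  cf <- rep(minor, 3)
  if (!is.na(major)) cf[major] <- 1 - 2 * minor else cf <- rep(1 / 3, 3)
  structure(list(species = quartet, cf = cf, n = NA_integer_),
            class = "quartet_cf")
}

#' @export
print.quartet_cf <- function(x, ...) {
  cat("Quartet:", paste(x$species, collapse = ", "), "\n")
  labs <- c(paste0(x$species[1], x$species[2], "|", x$species[3], x$species[4]),
            paste0(x$species[1], x$species[3], "|", x$species[2], x$species[4]),
            paste0(x$species[1], x$species[4], "|", x$species[2], x$species[3]))
  for (i in 1:3) cat(sprintf("  CF(%s) = %.4f\n", labs[i], x$cf[i]))
  if (!is.na(x$n)) cat("  n =", x$n, "gene trees\n")
  invisible(x)
}

#' Chi-squared goodness-of-fit of observed to expected concordance factors
#'
#' Per quartet, the observed topology counts `n * CF_obs` are compared with
#' expected counts `n * CF_exp` by Pearson chi-square (2 df per quartet);
#' the global statistic is the sum over quartets, with `2 * #quartets` df.
#' `P > 0.05` is read as the coalescent species tree adequately fitting the
#' gene-tree discordance (no need to invoke introgression). Quartets drawn
#' from one gene-tree set are not independent, so the global P value is an
#' approximation; this caveat is recorded in the result.
#'
#' @param observed A `quartet_cf` or list of them (with known `n`).
#' @param expected Matching `quartet_cf` or list (same quartets, same order).
#' @param eps Continuity floor applied to expected CFs of 0.
#' @return List with `statistic`, `df`, `p_value`, `per_quartet` data.frame,
#'   and `caveat`.
#' @export
cf_goodness_of_fit <- function(observed, expected, eps = 1e-8) {
  if (inherits(observed, "quartet_cf")) observed <- list(observed)
  if (inherits(expected, "quartet_cf")) expected <- list(expected)
  if (length(observed) == 0L) stop("empty quartet list")
  if (length(observed) != length(expected))
    stop("observed and expected lists differ in length")
  stat <- 0
  rows <- vector("list", length(observed))
  for (i in seq_along(observed)) {
    o <- observed[[i]]; e <- expected[[i]]
    if (!setequal(o$species, e$species))
      stop("quartet mismatch at position ", i)
    if (is.na(o$n) || o$n < 1) stop("observed CFs need a gene-tree count n")
    E <- e$cf
    if (any(E <= 0 & o$cf * o$n > 0) && eps <= 0)
      stop("expected CF of 0 with nonzero observed count")
    E <- pmax(E, eps)
    O <- o$cf * o$n
    Ecnt <- E * o$n
    s <- sum((O - Ecnt)^2 / Ecnt)
    stat <- stat + s
    rows[[i]] <- data.frame(quartet = paste(o$species, collapse = ","),
                            statistic = s, n = o$n)
  }
  df <- 2L * length(observed)
  structure(list(statistic = stat, df = df,
                 p_value = pchisq(stat, df, lower.tail = FALSE),
                 per_quartet = do.call(rbind, rows),
                 caveat = paste("quartets extracted from a shared gene-tree",
                                "set are not independent; the global P value",
                                "is approximate")),
            class = "cf_gof")
}

#' @export
print.cf_gof <- function(x, ...) {
  cat(sprintf("CF goodness-of-fit: X2 = %.4g, df = %d, P = %.4g\n",
              x$statistic, x$df, x$p_value))
  cat(" ", x$caveat, "\n")
  invisible(x)
}

#' Write a concordance-factor table as TSV
#'
#' @param cfs A `quartet_cf` or list of them.
#' @param file Output path; columns taxon1..taxon4, cf1..cf3, n.
#' @export
write_cf_table <- function(cfs, file) {
  if (inherits(cfs, "quartet_cf")) cfs <- list(cfs)
  rows <- lapply(cfs, function(x) {
    data.frame(taxon1 = x$species[1], taxon2 = x$species[2],
               taxon3 = x$species[3], taxon4 = x$species[4],
               cf1 = x$cf[1], cf2 = x$cf[2], cf3 = x$cf[3], n = x$n)
  })
  write.table(do.call(rbind, rows), file, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(file)
}
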