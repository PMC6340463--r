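# Deterministic transcriptome data-preparation rules: alignment occupancy
# filters, gene-tree QC, per-cluster transcript selection, fixed-nucleotide
# supermatrix concatenation and fourfold-degenerate site extraction.

#' Occupancy-filter a multiple sequence alignment
#'
#' Applies, in order: (1) remove columns with fewer than
#' `min_col_occupancy` non-gap characters (ambiguity codes count as
#' occupied); (2) remove sequences with more than `max_seq_gap_frac` gaps
#' over the surviving columns; (3) discard the whole alignment if fewer
#' than `min_species` species remain. Gap characters are `-`, `?` and `N`.
#'
#' @param aln Named character vector of equal-length aligned sequences.
#' @param min_col_occupancy Minimum fraction of occupied rows per column
#'   (default 0.10).
#' @param max_seq_gap_frac Maximum gap fraction per sequence (default 0.50).
#' @param min_species Minimum surviving species (default 4).
#' @param seq_species Named character vector mapping sequence names to
#'   species; default: sequence names are species.
#' @return List with `alignment` (possibly empty named vector), `discard`
#'   (logical: the whole alignment failed the species-count check), and
#'   `log` (data.frame of removed items with reason codes).
#' @export
filter_alignment <- function(aln, min_col_occupancy = 0.10,
                             max_seq_gap_frac = 0.50, min_species = 4,
                             seq_species = NULL) {
  if (!length(aln)) stop("empty alignment")
  if (min_col_occupancy < 0 || min_col_occupancy > 1 ||
      max_seq_gap_frac < 0 || max_seq_gap_frac > 1)
    stop("occupancy/gap thresholds must lie in [0, 1]")
  m <- matrix(unlist(strsplit(toupper(aln), ""), use.names = FALSE),
              nrow = length(aln), byrow = TRUE)
  rownames(m) <- names(aln)
  gap <- matrix(m %in% .MISSING_CHARS, nrow = nrow(m))
  log <- list()
  # columns first
  occ <- 1 - colMeans(gap)
  drop_col <- occ < min_col_occupancy
  if (any(drop_col)) {
    log[[length(log) + 1L]] <- data.frame(
      item = paste0("col", which(drop_col)), reason = "LOW_OCCUPANCY")
    m <- m[, !drop_col, drop = FALSE]
    gap <- gap[, !drop_col, drop = FALSE]
  }
  # then sequences
  gfrac <- if (ncol(m)) rowMeans(gap) else rep(1, nrow(m))
  drop_seq <- gfrac > max_seq_gap_frac
  if (any(drop_seq)) {
    log[[length(log) + 1L]] <- data.frame(
      item = rownames(m)[drop_seq], reason = "HIGH_GAP_FRACTION")
    m <- m[!drop_seq, , drop = FALSE]
  }
  # then the species count
  keep_names <- rownames(m)
  species <- if (is.null(seq_species)) keep_names
             else unname(seq_species[keep_names])
  n_species <- length(unique(species))
  discard <- n_species < min_species
  if (discard)
    log[[length(log) + 1L]] <- data.frame(item = "(alignment)",
                                          reason = "TOO_FEW_SPECIES")
  out <- setNames(apply(m, 1, paste, collapse = ""), keep_names)
  if (!nrow(m)) out <- setNames(character(0), character(0))
  list(alignment = out, discard = discard,
       log = if (length(log)) do.call(rbind, log)
             else data.frame(item = character(0), reason = character(0)))
}

#' Gene-tree sets
#'
#' A light container for per-gene trees with transcript-cluster ids,
#' SH-like node supports (as `node.label`), a tip-to-species map and a
#' designated outgroup species.
#'
#' @param trees List of `phylo` (or `multiPhylo`).
#' @param gene_id Character vector of gene/transcript ids.
#' @param cluster_id Character vector grouping alternative transcripts;
#'   default: each gene its own cluster.
#' @param tip_map Named character vector tip -> species; default:
#'   `<species>_<index>` or bare species tip labels.
#' @param outgroup Outgroup species label(s), if any.
#' @return An object of class `gene_tree_set`.
#' @export
gene_tree_set <- function(trees, gene_id = NULL, cluster_id = NULL,
                          tip_map = NULL, outgroup = NULL) {
  trees <- unclass(trees)
  n <- length(trees)
  if (is.null(gene_id)) gene_id <- sprintf("gene%04d", seq_len(n))
  if (is.null(cluster_id)) cluster_id <- gene_id
  stopifnot(length(gene_id) == n, length(cluster_id) == n)
  structure(list(trees = trees, gene_id = as.character(gene_id),
                 cluster_id = as.character(cluster_id), tip_map = tip_map,
                 outgroup = outgroup),
            class = "gene_tree_set")
}

#' @export
print.gene_tree_set <- function(x, ...) {
  cat("Gene-tree set:", length(x$trees), "trees,",
      length(unique(x$cluster_id)), "clusters\n")
  invisible(x)
}

.gts_subset <- function(gts, keep) {
  gene_tree_set(gts$trees[keep], gts$gene_id[keep], gts$cluster_id[keep],
                gts$tip_map, gts$outgroup)
}

#' Discard gene trees whose outgroup tips are not monophyletic
#'
#' Trees in which the outgroup tips present fail to form an exclusive clade
#' are dropped (a sign of unrealistic deep coalescence or misrooting);
#' trees with zero or one outgroup tip pass vacuously.
#'
#' @param gts A [gene_tree_set()] with a designated outgroup.
#' @return The retained [gene_tree_set()].
#' @export
outgroup_monophyly_filter <- function(gts) {
  stopifnot(inherits(gts, "gene_tree_set"))
  if (is.null(gts$outgroup)) stop("gene_tree_set has no designated outgroup")
  keep <- vapply(gts$trees, function(tr) {
    map <- .resolve_tip_map(tr$tip.label, gts$tip_map)
    og <- tr$tip.label[map %in% gts$outgroup]
    if (length(og) <= 1L) return(TRUE)
    is_exclusive_clade(tr, og)
  }, logical(1))
  .gts_subset(gts, keep)
}

#' Keep the best-supported transcript per cluster
#'
#' Per cluster, retains the single tree with the most nodes whose SH-like
#' support exceeds `support_threshold`; trees with no such node are
#' dropped, and clusters whose best tree has none disappear entirely. Ties
#' are broken by lexicographic gene id (deterministic).
#'
#' @param gts A [gene_tree_set()] with numeric node labels.
#' @param support_threshold Support must exceed this value (default 10).
#' @return The retained [gene_tree_set()], one tree per surviving cluster.
#' @export
select_transcript_per_cluster <- function(gts, support_threshold = 10) {
  stopifnot(inherits(gts, "gene_tree_set"))
  n_good <- vapply(gts$trees, function(tr) {
    supp <- suppressWarnings(as.numeric(tr$node.label))
    sum(supp > support_threshold, na.rm = TRUE)
  }, numeric(1))
  keep <- logical(length(gts$trees))
  for (cl in unique(gts$cluster_id)) {
    idx <- which(gts$cluster_id == cl)
    idx <- idx[n_good[idx] > 0]
    if (!length(idx)) next
    best <- idx[order(-n_good[idx], gts$gene_id[idx])][1]
    keep[best] <- TRUE
  }
  .gts_subset(gts, keep)
}

#' Concatenate per-gene species sequences into a supermatrix
#'
#' One row per species over the union of species; genes absent for a
#' species are filled with `N`. The partition table records each gene's
#' 1-based inclusive coordinate range (RAxML-style).
#'
#' @param alignments Named list (gene id) of named character vectors
#'   (species -> sequence).
#' @return List with `matrix` (named character vector per species) and
#'   `partitions` (data.frame gene/start/end).
#' @export
build_supermatrix <- function(alignments) {
  if (!length(alignments)) stop("empty gene list")
  if (anyDuplicated(names(alignments)))
    stop("duplicate gene ids: ",
         paste(unique(names(alignments)[duplicated(names(alignments))]),
               collapse = ", "))
  species <- sort(unique(unlist(lapply(alignments, names))))
  pieces <- matrix("", nrow = length(species), ncol = length(alignments),
                   dimnames = list(species, names(alignments)))
  start <- integer(length(alignments))
  end <- integer(length(alignments))
  pos <- 1L
  for (i in seq_along(alignments)) {
    aln <- alignments[[i]]
    L <- unique(nchar(aln))
    if (length(L) != 1L)
      stop("gene ", names(alignments)[i], ": unequal sequence lengths")
    blank <- strrep("N", L)
    pieces[, i] <- ifelse(species %in% names(aln), aln[species], blank)
    start[i] <- pos; end[i] <- pos + L - 1L; pos <- pos + L
  }
  mat <- setNames(apply(pieces, 1, paste, collapse = ""), species)
  list(matrix = mat,
       partitions = data.frame(gene = names(alignments), start = start,
                               end = end, stringsAsFactors = FALSE))
}

#' Write a RAxML-style partition file
#'
#' @param partitions Partition data.frame from [build_supermatrix()].
#' @param file Output path; lines of the form `DNA, gene = start-end`.
#' @export
write_partition_file <- function(partitions, file) {
  writeLines(sprintf("DNA, %s = %d-%d", partitions$gene, partitions$start,
                     partitions$end), file)
  invisible(file)
}

#' Extract fourfold-degenerate third-codon positions
#'
#' Emits the third position of every codon column at which, for every
#' non-missing species, the codon's first two bases place it in a fourfold
#' degenerate family (all four third-position bases synonymous, e.g. `GCx`
#' for alanine). Columns where any non-missing species sits in a non-4-fold
#' family are excluded; species missing at a column contribute `N` to the
#' emitted site. Such sites evolve approximately neutrally and are the
#' standard substrate for clock-like supermatrix inference.
#'
#' @param alignments Named list (gene) of named character vectors of
#'   codon-aligned CDS.
#' @param code Optional genetic-code table.
#' @return List with `sites` (named character vector, per-species
#'   concatenated third positions) and `map` (data.frame gene/codon of each
#'   emitted site).
#' @export
extract_fourfold_sites <- function(alignments, code = NULL) {
  if (!length(alignments)) stop("empty gene list")
  ff <- .fourfold_prefixes(code)
  species <- sort(unique(unlist(lapply(alignments, names))))
  out <- lapply(species, function(s) character(0))
  names(out) <- species
  map <- list()
  for (g in names(alignments)) {
    cm <- .codon_matrix(alignments[[g]])
    miss <- .codon_missing(cm)
    dim(miss) <- dim(cm)
    pref_ok <- matrix(substr(cm, 1, 2) %in% ff, nrow(cm))
    keep <- apply(pref_ok | miss, 2, all) & !apply(miss, 2, all)
    if (!any(keep)) next
    third <- matrix(substr(cm, 3, 3), nrow(cm))
    third[miss] <- "N"
    for (s in species) {
      add <- if (s %in% rownames(cm)) third[match(s, rownames(cm)), keep]
             else rep("N", sum(keep))
      out[[s]] <- c(out[[s]], add)
    }
    map[[length(map) + 1L]] <- data.frame(gene = g, codon = which(keep),
                                          stringsAsFactors = FALSE)
  }
  list(sites = vapply(out, paste, character(1), collapse = ""),
       map = if (length(map)) do.call(rbind, map)
             else data.frame(gene = character(0), codon = integer(0)))
}
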