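# Tree data model, newick I/O, coalescent-unit conventions, topological queries.
# Trees are ape "phylo" objects throughout; internal-node support values live
# in tree$node.label (the common newick internal-label dialect).

#' Parse a newick string into a rooted tree
#'
#' Thin, validating wrapper around [ape::read.tree()]. Internal-node labels
#' are kept as (typically numeric) support values. Branch lengths absent from
#' the string default to 0, with a warning, so topology-only trees (e.g.
#' ASTRAL output) remain loadable for concordance-factor counting.
#'
#' @param text A single newick string, semicolon-terminated.
#' @return An object of class `phylo`.
#' @export
#' @examples
#' tr <- parse_newick("((A:1,B:1)95:2,C:3);")
#' tr$node.label
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  .check_newick_syntax(text)
  tr <- ape::read.tree(text = text)
  if (is.null(tr)) stop("newick parse error in: ", substr(text, 1, 60))
  if (anyDuplicated(tr$tip.label))
    stop("duplicate tip labels: ",
         paste(unique(tr$tip.label[duplicated(tr$tip.label)]), collapse = ", "))
  if (is.null(tr$edge.length)) {
    warning("newick string has no branch lengths; defaulting all to 0")
    tr$edge.length <- rep(0, nrow(tr$edge))
  }
  if (any(is.na(tr$edge.length)))
    stop("tree mixes present and absent branch lengths")
  if (any(tr$edge.length < 0))
    stop("negative branch length in newick input")
  tr
}

# character-offset diagnostics ape does not provide
.check_newick_syntax <- function(text) {
  chars <- strsplit(text, "")[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop("malformed newick: unmatched ')' at character offset ", i)
    }
  }
  if (depth > 0L)
    stop("malformed newick: ", depth, " unclosed '(' by character offset ",
         length(chars))
  if (!grepl(";", text))
    stop("malformed newick: missing terminating ';' at character offset ",
         length(chars))
  invisible(TRUE)
}

#' Serialize a tree to newick
#'
#' @param tree A `phylo` object.
#' @param digits Significant digits for branch lengths.
#' @return A newick string (semicolon-terminated).
#' @export
write_newick <- function(tree, digits = 12) {
  ape::write.tree(tree, digits = digits)
}

#' Read / write multi-tree newick files
#'
#' One or more semicolon-terminated trees per file.
#'
#' @param file Path to a newick file.
#' @return `read_newick_trees()`: a `multiPhylo` list (even for one tree).
#' @export
read_newick_trees <- function(file) {
  tr <- ape::read.tree(file)
  if (inherits(tr, "phylo")) tr <- c(tr)
  tr
}

#' @rdname read_newick_trees
#' @param trees A `phylo` or `multiPhylo`.
#' @export
write_newick_trees <- function(trees, file) {
  ape::write.tree(trees, file = file)
  invisible(file)
}

#' Coalescent-unit conventions
#'
#' A unit convention fixes how many generations one branch-length unit
#' represents, as a multiple of the effective population size Ne:
#' `SNAQ` = 1 x Ne generations per unit (the definition stated alongside the
#' SNaQ-derived species trees this package consumes; note that much of the
#' coalescent literature instead uses 2 x Ne, available here as `COAL`),
#' `MS` = 4 x Ne (the ms simulator scale), `COAL` = 2 x Ne (the scale on
#' which the minor quartet concordance factor is exp(-t)/3), and `TIME` for
#' absolute time (not convertible to the others without Ne and generation
#' time). Organelle genomes have a smaller Ne; `organelle_ne_fraction`
#' (default 1/4, for mitochondria in a diploid nuclear background) governs
#' the rescaling applied by [convert_branch_lengths()] with
#' `organelle = TRUE`.
#'
#' @param name One of "SNAQ", "MS", "COAL", "TIME".
#' @param ne_multiplier Generations per unit as a multiple of Ne; defaults to
#'   the convention's standard value. Must be a positive number.
#' @param organelle_ne_fraction Organellar Ne as a fraction of nuclear Ne.
#' @return An object of class `unit_convention`.
#' @export
unit_convention <- function(name = c("SNAQ", "MS", "COAL", "TIME"),
                            ne_multiplier = NULL,
                            organelle_ne_fraction = 0.25) {
  name <- match.arg(name)
  default <- c(SNAQ = 1, MS = 4, COAL = 2, TIME = NA_real_)[[name]]
  if (is.null(ne_multiplier)) ne_multiplier <- default
  if (name != "TIME" && (!is.numeric(ne_multiplier) || ne_multiplier <= 0))
    stop("ne_multiplier must be strictly positive")
  if (organelle_ne_fraction <= 0)
    stop("organelle_ne_fraction must be strictly positive")
  structure(list(name = name, ne_multiplier = ne_multiplier,
                 organelle_ne_fraction = organelle_ne_fraction),
            class = "unit_convention")
}

#' A species tree with branch lengths in coalescent units
#'
#' Bundles a rooted `phylo` with the [unit_convention()] of its branch
#' lengths. Branch lengths must be non-negative; `Inf` is permitted and is
#' interpreted by the simulator as forced monophyly (lineages below an
#' infinite branch always coalesce before reaching its top).
#'
#' @param tree A rooted `phylo`, or a newick string.
#' @param convention A [unit_convention()] (default SNAQ).
#' @return An object of class `species_tree_cu`.
#' @export
species_tree_cu <- function(tree, convention = unit_convention("SNAQ")) {
  if (is.character(tree)) tree <- parse_newick(tree)
  stopifnot(inherits(tree, "phylo"), inherits(convention, "unit_convention"))
  # the basal node is taken as the root population; basal polytomies
  # (e.g. star trees) are legitimate rooted MSC inputs
  if (is.null(tree$edge.length)) stop("species tree needs branch lengths")
  if (any(is.nan(tree$edge.length)) || any(tree$edge.length < 0))
    stop("branch lengths must be non-negative (Inf = forced monophyly)")
  structure(list(tree = tree, convention = convention),
            class = "species_tree_cu")
}

#' @export
print.species_tree_cu <- function(x, ...) {
  cat("Species tree in", x$convention$name, "coalescent units (",
      ape::Ntip(x$tree), "tips )\n")
  invisible(x)
}

#' Convert species-tree branch lengths between coalescent-unit conventions
#'
#' A length of L units of `m_src * Ne` generations equals
#' `L * m_src / m_tgt` units of `m_tgt * Ne` generations. With
#' `organelle = TRUE` the lengths are first divided by the organellar Ne
#' fraction (default 1/4, i.e. multiplied by 4) to express them on the
#' organelle's own Ne before the convention change: the SNAQ-to-MS organelle
#' conversion (x4 then /4) is therefore the identity map on lengths.
#'
#' @param x A [species_tree_cu()].
#' @param target A [unit_convention()] or a convention name.
#' @param organelle Apply the organellar Ne rescaling first?
#' @return A [species_tree_cu()] in the target convention.
#' @export
convert_branch_lengths <- function(x, target, organelle = FALSE) {
  stopifnot(inherits(x, "species_tree_cu"))
  if (is.character(target)) target <- unit_convention(target)
  stopifnot(inherits(target, "unit_convention"))
  src <- x$convention
  if (src$name == "TIME" || target$name == "TIME")
    stop("TIME branch lengths are not convertible to coalescent units ",
         "without Ne and generation time")
  factor <- src$ne_multiplier / target$ne_multiplier
  if (organelle) factor <- factor / src$organelle_ne_fraction
  out <- x$tree
  out$edge.length <- out$edge.length * factor
  species_tree_cu(out, target)
}

#' Is a set of taxa an exclusive clade?
#'
#' TRUE iff the smallest clade containing `taxa` contains no other tips.
#'
#' @param tree A rooted `phylo`.
#' @param taxa Character vector of tip labels (length >= 1).
#' @return Logical scalar.
#' @export
is_exclusive_clade <- function(tree, taxa) {
  stopifnot(inherits(tree, "phylo"))
  missing <- setdiff(taxa, tree$tip.label)
  if (length(missing))
    stop("tip label(s) not in tree: ", paste(missing, collapse = ", "))
  taxa <- unique(taxa)
  if (length(taxa) == 1L) return(TRUE)
  if (length(taxa) == ape::Ntip(tree)) return(TRUE)
  mrca <- ape::getMRCA(tree, taxa)
  setequal(.tips_under(tree, mrca), taxa)
}

# tip labels descending from an internal node
.tips_under <- function(tree, node) {
  ntip <- ape::Ntip(tree)
  if (node <= ntip) return(tree$tip.label[node])
  todo <- node
  tips <- integer(0)
  edge <- tree$edge
  while (length(todo)) {
    kids <- edge[edge[, 1] %in% todo, 2]
    tips <- c(tips, kids[kids <= ntip])
    todo <- kids[kids > ntip]
  }
  tree$tip.label[tips]
}

#' Collapse poorly supported internal branches into polytomies
#'
#' Contracts every internal branch whose child node carries a support value
#' below `threshold` (supports are read from `tree$node.label`). The tip set
#' is unchanged; the contracted branch's length is discarded, as in
#' [ape::di2multi()]. Internal nodes without a support value are collapsed
#' only when `collapse_unsupported = TRUE`.
#'
#' @param tree A rooted `phylo` with supports as internal-node labels.
#' @param threshold Support threshold; nodes with support < threshold are
#'   collapsed. Must be non-negative.
#' @param collapse_unsupported Treat missing supports as below threshold?
#' @return A `phylo`, possibly with polytomies.
#' @export
collapse_low_support <- function(tree, threshold, collapse_unsupported = FALSE) {
  stopifnot(inherits(tree, "phylo"))
  if (threshold < 0) stop("threshold must be non-negative")
  ntip <- ape::Ntip(tree)
  nnode <- tree$Nnode
  root <- ntip + 1L
  supp <- suppressWarnings(as.numeric(tree$node.label))
  if (is.null(tree$node.label)) supp <- rep(NA_real_, nnode)
  drop <- logical(ntip + nnode)
  for (nd in (ntip + 1L):(ntip + nnode)) {
    if (nd == root) next
    s <- supp[nd - ntip]
    low <- if (is.na(s)) collapse_unsupported else s < threshold
    if (low) drop[nd] <- TRUE
  }
  if (!any(drop)) return(tree)
  .contract_nodes(tree, which(drop))
}

# contract edges above the given internal nodes; rebuild via newick to keep
# ape's node-numbering invariants without bookkeeping
.contract_nodes <- function(tree, nodes) {
  ntip <- ape::Ntip(tree)
  root <- ntip + 1L
  parent <- integer(ntip + tree$Nnode)
  elen <- numeric(ntip + tree$Nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  if (!is.null(tree$edge.length)) elen[tree$edge[, 2]] <- tree$edge.length
  supp <- tree$node.label
  keep_children <- function(nd) {
    kids <- tree$edge[tree$edge[, 1] == nd, 2]
    out <- integer(0)
    for (k in kids) {
      if (k %in% nodes) out <- c(out, keep_children(k)) else out <- c(out, k)
    }
    out
  }
  build <- function(nd) {
    if (nd <= ntip) {
      lab <- tree$tip.label[nd]
      return(paste0(lab, ":", format(elen[nd], digits = 15)))
    }
    kids <- keep_children(nd)
    sub <- vapply(kids, build, character(1))
    lab <- if (!is.null(supp)) supp[nd - ntip] else ""
    if (is.na(lab)) lab <- ""
    if (nd == root)
      paste0("(", paste(sub, collapse = ","), ")", lab)
    else
      paste0("(", paste(sub, collapse = ","), ")", lab, ":",
             format(elen[nd], digits = 15))
  }
  parse_newick(paste0(build(root), ";"))
}

#' Variance of root-to-tip path lengths
#'
#' Population variance (denominator n) of the distances from the root to
#' every tip; 0 for ultrametric trees and for a single tip.
#'
#' @param tree A rooted `phylo` with branch lengths.
#' @return Non-negative real.
#' @export
root_to_tip_variance <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (!ape::is.rooted(tree)) stop("root_to_tip_variance needs a rooted tree")
  d <- tip_depths(tree)$depth
  mean((d - mean(d))^2)
}

#' Root-to-tip depths
#'
#' @param tree A rooted `phylo` with branch lengths.
#' @return A data.frame with columns `tip` and `depth`.
#' @export
tip_depths <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  nd <- ape::node.depth.edgelength(tree)
  data.frame(tip = tree$tip.label, depth = nd[seq_len(ape::Ntip(tree))],
             stringsAsFactors = FALSE)
}

#' @rdname tip_depths
#' @param file Output TSV path.
#' @export
write_tip_depths <- function(tree, file) {
  write.table(tip_depths(tree), file, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(file)
}

#' A dated ultrametric tree
#'
#' Wraps a `phylo` whose branch lengths are in millions of years. When
#' `ultrametric = TRUE` (the default), root-to-tip path lengths must agree
#' within `tol`.
#'
#' @param tree A rooted `phylo` (or newick string) with branch lengths in My.
#' @param ultrametric Enforce equal root-to-tip depths?
#' @param tol Absolute tolerance on depth differences.
#' @return An object of class `time_tree`.
#' @export
time_tree <- function(tree, ultrametric = TRUE, tol = 1e-6) {
  if (is.character(tree)) tree <- parse_newick(tree)
  stopifnot(inherits(tree, "phylo"))
  if (!ape::is.rooted(tree)) stop("time tree must be rooted")
  if (ultrametric) {
    d <- tip_depths(tree)$depth
    if (diff(range(d)) > tol)
      stop("tree is not ultrametric within tolerance ", tol)
  }
  structure(list(tree = tree, ultrametric = ultrametric),
            class = "time_tree")
}
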