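# Evolutionary distinctness (ED) from a dated tree and EDGE conservation
# scoring from ED plus IUCN threat category.

.GE_LEVELS <- c(LC = 0L, NT = 1L, VU = 2L, EN = 3L, CR = 4L, DD = NA_integer_)

#' Per-tip evolutionary distinctness
#'
#' Fair-proportion apportionment (the default): each branch's length is
#' divided equally among its descendant tips, and a tip's ED is the sum of
#' its shares along the root-to-tip path — so ED sums to the total tree
#' length over tips. The equal-splits alternative halves a branch's
#' contribution at every intervening split instead (it does not conserve
#' total length).
#'
#' @param tree A rooted `phylo` (or [time_tree()]) with non-negative branch
#'   lengths, typically in My.
#' @param method `"fair.proportion"` (default) or `"equal.splits"`.
#' @return Named numeric vector of ED scores, one per tip.
#' @export
#' @examples
#' evolutionary_distinctness(parse_newick("((A:1,B:1):1,C:2);"))
evolutionary_distinctness <- function(tree,
                                      method = c("fair.proportion",
                                                 "equal.splits")) {
  method <- match.arg(method)
  if (inherits(tree, "time_tree")) tree <- tree$tree
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) stop("tree needs branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch length")
  ntip <- ape::Ntip(tree)
  ed <- setNames(numeric(ntip), tree$tip.label)
  # per-edge descendant tips via one postorder sweep
  po <- ape::reorder.phylo(tree, "postorder")
  ndesc <- c(rep(1L, ntip), integer(tree$Nnode))
  tipsets <- c(lapply(seq_len(ntip), identity),
               vector("list", tree$Nnode))
  for (i in seq_len(nrow(po$edge))) {
    p <- po$edge[i, 1]; ch <- po$edge[i, 2]
    ndesc[p] <- ndesc[p] + ndesc[ch]
    tipsets[[p]] <- c(tipsets[[p]], tipsets[[ch]])
  }
  if (method == "fair.proportion") {
    for (i in seq_len(nrow(po$edge))) {
      ch <- po$edge[i, 2]
      tips <- tipsets[[ch]]
      ed[tips] <- ed[tips] + po$edge.length[i] / ndesc[ch]
    }
  } else {
    # equal splits: walk root-to-tip, halving at every split passed below
    # the edge (division by the product of child counts of crossed nodes)
    parent <- integer(ntip + tree$Nnode)
    elen <- numeric(ntip + tree$Nnode)
    parent[tree$edge[, 2]] <- tree$edge[, 1]
    elen[tree$edge[, 2]] <- tree$edge.length
    nchild <- table(factor(tree$edge[, 1], levels = seq_len(ntip + tree$Nnode)))
    root <- ntip + 1L
    for (tip in seq_len(ntip)) {
      node <- tip
      div <- 1
      while (node != root) {
        ed[tip] <- ed[tip] + elen[node] / div
        node <- parent[node]
        div <- div * as.numeric(nchild[node])
      }
    }
  }
  ed
}

#' EDGE score
#'
#' `EDGE = ln(1 + ED) + GE * ln(2)`, combining evolutionary distinctness
#' with the IUCN threat category encoded as GE (LC = 0, NT = 1, VU = 2,
#' EN = 3, CR = 4). A missing GE (data-deficient species) yields `NA`, not
#' 0: the score is undefined, and such species flag a data-gathering need
#' rather than a low priority.
#'
#' @param ed Evolutionary distinctness (>= 0); vectorized.
#' @param ge Integer threat score 0-4, or NA for data-deficient.
#' @return Numeric EDGE score(s); report rounded to 1 decimal by
#'   convention.
#' @export
#' @examples
#' edge_score(9.6, 4)   # critically endangered, highly distinct
edge_score <- function(ed, ge) {
  stopifnot(is.numeric(ed), all(ed >= 0))
  ge_ok <- is.na(ge) | (ge %in% 0:4)
  if (!all(ge_ok)) stop("GE must be an integer in 0..4 or NA")
  ifelse(is.na(ge), NA_real_, log(1 + ed) + ge * log(2))
}

#' Map IUCN red-list categories to GE scores
#'
#' Accepts the two-letter codes (LC, NT, VU, EN, CR, DD) or full category
#' names (case-insensitive); DD / data-deficient maps to NA.
#'
#' @param category Character vector of IUCN categories.
#' @return Integer vector of GE scores (NA for data-deficient).
#' @export
iucn_ge <- function(category) {
  key <- toupper(trimws(as.character(category)))
  full <- c("LEAST CONCERN" = "LC", "NEAR-THREATENED" = "NT",
            "NEAR THREATENED" = "NT", "VULNERABLE" = "VU",
            "ENDANGERED" = "EN", "CRITICALLY ENDANGERED" = "CR",
            "DATA DEFICIENT" = "DD", "DATA-DEFICIENT" = "DD")
  key <- ifelse(key %in% names(full), full[key], key)
  unknown <- setdiff(unique(key), names(.GE_LEVELS))
  if (length(unknown))
    stop("unknown IUCN category: ", paste(unknown, collapse = ", "))
  unname(.GE_LEVELS[key])
}

#' Build an ED/GE/EDGE table from a dated tree and threat categories
#'
#' @param tree A [time_tree()] or rooted `phylo` with branch lengths in My.
#' @param iucn Data.frame with columns `species` and `iucn_category`, or a
#'   named character vector of categories; species absent from it get NA
#'   GE.
#' @param method ED method, see [evolutionary_distinctness()].
#' @return Data.frame with columns species, ed, iucn_category, ge, edge
#'   (edge rounded to 1 decimal in the `edge_1dp` column, full precision in
#'   `edge`).
#' @export
edge_table <- function(tree, iucn, method = "fair.proportion") {
  ed <- evolutionary_distinctness(tree, method = method)
  if (is.data.frame(iucn)) {
    stopifnot(all(c("species", "iucn_category") %in% names(iucn)))
    cat_map <- setNames(iucn$iucn_category, iucn$species)
  } else cat_map <- iucn
  category <- unname(cat_map[names(ed)])
  ge <- iucn_ge(ifelse(is.na(category), "DD", category))
  edge <- edge_score(ed, ge)
  data.frame(species = names(ed), ed = unname(ed),
             iucn_category = category, ge = ge, edge = unname(edge),
             edge_1dp = round(unname(edge), 1), stringsAsFactors = FALSE)
}
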