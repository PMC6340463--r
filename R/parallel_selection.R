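# PhyloGWAS: detection of nonsynonymous substitutions shared by a
# non-monophyletic phenotype group, and the simulated single-mutation ILS
# null with missing-taxa weighting.

#' Focal-group specification for the parallel-selection scan
#'
#' @param focal Character vector of focal (phenotype-sharing) species; may
#'   be non-monophyletic on the species tree.
#' @param required_present Species that must have data at a site for it to
#'   be counted; the focal species are always required and need not be
#'   listed.
#' @param max_missing Maximum number of missing taxa tolerated at a codon
#'   site (default 2).
#' @param ingroup Optional character vector restricting the "non-focal must
#'   differ" contrast (e.g. to exclude an outgroup); default: all species
#'   present in the data.
#' @return An object of class `group_spec`.
#' @export
group_spec <- function(focal, required_present = character(),
                       max_missing = 2L, ingroup = NULL) {
  focal <- unique(as.character(focal))
  if (!length(focal)) stop("focal group must be non-empty")
  required_present <- union(focal, required_present)
  structure(list(focal = focal, required_present = required_present,
                 max_missing = as.integer(max_missing), ingroup = ingroup),
            class = "group_spec")
}

#' Collapse per-individual sequences to a fixed-nucleotide species consensus
#'
#' A site is emitted as a fixed nucleotide iff every non-missing individual
#' carries the same unambiguous base (A, C, G or T); polymorphic sites and
#' sites carrying only IUPAC heterozygote codes are emitted as missing
#' (`N`). Sites missing in all individuals are missing.
#'
#' @param individual_seqs Character vector of equal-length CDS strings, one
#'   per individual of a single species.
#' @return A single consensus CDS string.
#' @export
fix_species_sequence <- function(individual_seqs) {
  if (!length(individual_seqs)) stop("need at least one individual")
  seqs <- toupper(individual_seqs)
  L <- unique(nchar(seqs))
  if (length(L) != 1L)
    stop("individuals differ in sequence length: ",
         paste(unique(nchar(seqs)), collapse = ", "))
  m <- matrix(unlist(strsplit(seqs, ""), use.names = FALSE),
              nrow = length(seqs), byrow = TRUE)
  out <- apply(m, 2, function(col) {
    obs <- col[!(col %in% .MISSING_CHARS)]
    if (!length(obs)) return("N")
    u <- unique(obs)
    if (length(u) == 1L && u %in% c("A", "C", "G", "T")) u else "N"
  })
  paste(out, collapse = "")
}

#' Classify a codon site across species
#'
#' Applies the parallel-selection site filters: a site is retained iff the
#' number of distinct amino-acid states among non-missing species is at most
#' `max_states` (default 2; more states likely reflect multiple changes
#' rather than sorting of one ancestral variant) and at most `max_missing`
#' taxa are missing. Codons containing gaps, `N` or ambiguity codes count as
#' missing for that species.
#'
#' @param codons Named character vector, one codon per species.
#' @param code Optional genetic-code table (named 64-vector); default
#'   standard nuclear code.
#' @param max_states Maximum distinct amino-acid states.
#' @param max_missing Maximum missing taxa.
#' @return List with `aa` (named amino acids, NA = missing), `n_states`,
#'   `missing` (species), `retained`.
#' @export
classify_codon_site <- function(codons, code = NULL, max_states = 2L,
                                max_missing = 2L) {
  codons <- toupper(codons)
  bad <- !grepl("^[ACGTRYSWKMBDHVN?-]{3}$", codons)
  if (any(bad))
    stop("invalid codon characters in: ", paste(codons[bad], collapse = ", "))
  miss <- .codon_missing(codons)
  aa <- rep(NA_character_, length(codons))
  aa[!miss] <- .translate_codons(codons[!miss], code)
  names(aa) <- names(codons)
  n_states <- length(unique(aa[!is.na(aa)]))
  list(aa = aa, n_states = n_states, missing = names(codons)[miss],
       retained = n_states <= max_states && sum(miss) <= max_missing)
}

#' Scan codon alignments for group-shared nonsynonymous substitutions
#'
#' The core of the PhyloGWAS scan. A codon site qualifies iff it passes
#' [classify_codon_site()]'s filters (at most 2 amino-acid states, at most
#' `max_missing` missing taxa), every required species has data, all focal
#' species share one amino acid, and every non-missing non-focal species in
#' the contrast set carries the other amino acid. `n_var` counts all
#' retained, required-complete sites with at least two amino-acid states
#' among non-missing species — the denominator of the excess test. Genes
#' are counted once however many sites qualify. The missingness
#' configurations (which taxa were missing) of the `n_var` sites are
#' tabulated for the weighting of the simulated null.
#'
#' @param alignments Codon-alignment set: named list (genes) of named
#'   character vectors (species-level, codon-aligned CDS).
#' @param group A [group_spec()].
#' @param code Optional genetic-code table.
#' @return An object of class `shared_substitution_report`: list with
#'   `sites` (data.frame: gene, codon, focal_aa, other_aa, missing),
#'   `s_genes`, `s_sites`, `n_var`, `missing_configs` (data.frame: config,
#'   freq), `group`.
#' @export
find_shared_substitutions <- function(alignments, group, code = NULL) {
  stopifnot(inherits(group, "group_spec"))
  if (!length(alignments)) stop("empty alignment set")
  species_universe <- unique(unlist(lapply(alignments, names)))
  miss_sp <- setdiff(group$required_present, species_universe)
  if (length(miss_sp))
    stop("required species absent from alignments: ",
         paste(miss_sp, collapse = ", "))
  if (all(species_universe %in% group$focal))
    stop("focal group covers all species; the contrast is undefined")
  contrast <- if (is.null(group$ingroup)) species_universe else group$ingroup
  code <- .genetic_code(code)
  aa_levels <- sort(unique(code))
  rows <- list()
  n_var <- 0L
  config_counts <- new.env(parent = emptyenv())
  s_genes <- character(0)
  for (g in names(alignments)) {
    cm <- .codon_matrix(alignments[[g]])
    sp <- rownames(cm)
    in_focal <- sp %in% group$focal
    in_req <- sp %in% group$required_present
    other_rows <- which(!in_focal & sp %in% contrast)
    missm <- .codon_missing(cm)
    dim(missm) <- dim(cm)
    aam <- matrix(NA_character_, nrow(cm), ncol(cm))
    aam[!missm] <- .translate_codons(cm[!missm], code)
    # amino acids as bit positions; missing contributes no bit
    bits <- matrix(0L, nrow(cm), ncol(cm))
    ok <- !is.na(aam)
    bits[ok] <- bitwShiftL(1L, match(aam[ok], aa_levels) - 1L)
    colmask <- 0L
    for (r in seq_len(nrow(bits))) colmask <- bitwOr(colmask, bits[r, ])
    n_states <- integer(ncol(cm))
    for (lv in seq_along(aa_levels)) {
      bit <- bitwShiftL(1L, lv - 1L)
      n_states <- n_states + (bitwAnd(colmask, bit) > 0L)
    }
    nmiss <- colSums(missm)
    req_ok <- colSums(missm[in_req, , drop = FALSE]) == 0L
    tested <- n_states <= 2L & nmiss <= group$max_missing & req_ok &
      n_states >= 2L
    if (any(tested)) {
      n_var <- n_var + sum(tested)
      complete <- sum(tested & nmiss == 0L)
      if (complete)
        config_counts[["."]] <- (config_counts[["."]] %||% 0L) + complete
      for (j in which(tested & nmiss > 0L)) {
        key <- paste(sort(sp[missm[, j]]), collapse = ",")
        config_counts[[key]] <- (config_counts[[key]] %||% 0L) + 1L
      }
      # focal species share one amino acid...
      fr <- which(in_focal)
      fa <- aam[fr[1], ]
      unif <- !is.na(fa)
      for (r in fr[-1]) unif <- unif & !is.na(aam[r, ]) & aam[r, ] == fa
      # ...and all non-missing non-focal contrast species the other
      omask <- 0L
      for (r in other_rows) omask <- bitwOr(omask, bits[r, ])
      one_other <- bitwAnd(omask, omask - 1L) == 0L & omask > 0L
      fa_bit <- ifelse(is.na(fa), 0L,
                       bitwShiftL(1L, match(fa, aa_levels) - 1L))
      qual <- tested & unif & one_other & omask != fa_bit
      for (j in which(qual)) {
        rows[[length(rows) + 1L]] <-
          data.frame(gene = g, codon = j, focal_aa = fa[j],
                     other_aa = aa_levels[which(
                       bitwAnd(omask[j], bitwShiftL(1L, seq_along(aa_levels) - 1L)) > 0L)],
                     missing = paste(sort(sp[missm[, j]]), collapse = ","),
                     stringsAsFactors = FALSE)
        s_genes <- union(s_genes, g)
      }
    }
  }
  sites <- if (length(rows)) do.call(rbind, rows)
  else data.frame(gene = character(0), codon = integer(0),
                  focal_aa = character(0), other_aa = character(0),
                  missing = character(0), stringsAsFactors = FALSE)
  cfg_names <- ls(config_counts, all.names = TRUE)
  cfg <- data.frame(config = cfg_names,
                    count = vapply(cfg_names, function(k) config_counts[[k]],
                                   integer(1)),
                    stringsAsFactors = FALSE)
  cfg$freq <- if (n_var > 0) cfg$count / n_var else numeric(nrow(cfg))
  structure(list(sites = sites, s_genes = length(s_genes),
                 s_sites = nrow(sites), n_var = n_var,
                 missing_configs = cfg[order(cfg$config), , drop = FALSE],
                 group = group),
            class = "shared_substitution_report")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.shared_substitution_report <- function(x, ...) {
  cat("Shared nonsynonymous substitutions:",
      x$s_sites, "site(s) in", x$s_genes, "gene(s);",
      "n_var =", x$n_var, "variable amino-acid sites tested\n")
  invisible(x)
}

#' Estimate the ILS probability of a group-shared substitution pattern
#'
#' Monte-Carlo estimate of the per-site probability, under the MSC over the
#' species tree with a single mutation per gene (diploid sampling: two
#' chromosomes per species), that the mutation produces a fixed amino-acid
#' difference separating the focal group from everything else. Matching
#' requires both chromosomes of every focal species to share one state and
#' both chromosomes of every non-ignored non-focal species the other
#' (fixation within species). The estimate is the missingness-weighted
#' mixture over the observed configurations:
#' p-hat = sum_c freq(c) * Pr(match with taxa in c ignored), with all
#' configurations evaluated on a common simulation stream.
#'
#' @param species_tree A [species_tree_cu()].
#' @param group A [group_spec()].
#' @param missing_configs Data.frame with columns `config`
#'   (comma-separated missing species, `"."` or `""` for none) and `freq`
#'   (summing to 1), as produced by [find_shared_substitutions()]; default:
#'   no missingness.
#' @param n_sims Number of simulated single-mutation genes (default 1e6;
#'   scale up towards 1e8 for publication-grade tail estimates).
#' @param polarity `"either"` (default; fixed differences are unpolarized)
#'   or `"derived-in-group"`.
#' @param chroms_per_species Chromosomes sampled per species (default 2,
#'   diploid).
#' @param condition_on_tested Report probabilities per *testable* simulated
#'   site (default TRUE). A simulated site is testable under a
#'   configuration iff every non-ignored species is fixed (within-species
#'   polymorphism becomes missing data in the fixed-nucleotide consensus)
#'   and the site still segregates between species — the condition a real
#'   site must meet to be counted in `n_var`. Without conditioning, the
#'   denominator includes simulated mutations that could never appear among
#'   the tested sites, and the excess test is anti-conservative.
#' @param seed Optional integer seed.
#' @param keep_indicators Also return the per-simulation 0/1 match stream
#'   (each simulation assigned one configuration drawn by frequency;
#'   non-testable simulations are dropped when conditioning), for the
#'   dataset-grouping P value.
#' @return An object of class `ils_pattern_prob`: list with `p_hat`, `se`,
#'   `n_sims`, `per_config` (data.frame config/freq/matches/tested), and
#'   optionally `indicators`.
#' @export
estimate_ils_pattern_probability <- function(species_tree, group,
                                             missing_configs = NULL,
                                             n_sims = 1e6,
                                             polarity = c("either",
                                                          "derived-in-group"),
                                             chroms_per_species = 2L,
                                             condition_on_tested = TRUE,
                                             seed = NULL,
                                             keep_indicators = FALSE) {
  stopifnot(inherits(species_tree, "species_tree_cu"),
            inherits(group, "group_spec"))
  polarity <- match.arg(polarity)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(missing_configs))
    missing_configs <- data.frame(config = ".", freq = 1)
  w <- missing_configs$freq
  if (abs(sum(w) - 1) > 1e-8)
    stop("missing-configuration frequencies must sum to 1")
  sp <- .st_prep(species_tree, as.integer(chroms_per_species),
                 allow_inf = FALSE)
  tips <- sp$tips
  bad <- setdiff(group$focal, tips)
  if (length(bad))
    stop("focal species not in species tree: ", paste(bad, collapse = ", "))
  # species roles: 0 focal, 1 contrast (non-focal ingroup), 2 free
  ingroup <- if (is.null(group$ingroup)) tips else group$ingroup
  role <- ifelse(tips %in% group$focal, 0L,
                 ifelse(tips %in% ingroup, 1L, 2L))
  chrom_sp <- match(sp$chrom_species, tips) - 1L
  configs <- lapply(missing_configs$config, function(cfg) {
    taxa <- if (cfg %in% c("", ".")) character(0)
            else strsplit(cfg, ",", fixed = TRUE)[[1]]
    hit <- intersect(taxa, group$required_present)
    if (length(hit))
      stop("missingness configuration ignores required species: ",
           paste(hit, collapse = ", "))
    match(taxa, tips) - 1L
  })
  res <- cpp_pattern_prob(sp$parent, sp$height, sp$order, sp$n_tip,
                          sp$samples, as.integer(n_sims), chrom_sp, role,
                          configs, w, polarity == "either",
                          condition_on_tested, keep_indicators)
  denom <- if (condition_on_tested) pmax(res$tested, 1L) else n_sims
  p_c <- res$match / denom
  p_hat <- sum(w * p_c)
  se <- sqrt(sum(w^2 * p_c * (1 - p_c) / denom))
  out <- list(p_hat = p_hat, se = se, n_sims = n_sims,
              per_config = data.frame(config = missing_configs$config,
                                      freq = w, matches = res$match,
                                      tested = res$tested,
                                      p = p_c),
              polarity = polarity,
              condition_on_tested = condition_on_tested)
  if (keep_indicators) out$indicators <- res$indicators
  structure(out, class = "ils_pattern_prob")
}

#' @export
print.ils_pattern_prob <- function(x, ...) {
  cat(sprintf("ILS pattern probability: p-hat = %.3g (SE %.2g, %g sims)\n",
              x$p_hat, x$se, x$n_sims))
  invisible(x)
}

#' PhyloGWAS excess P value
#'
#' Compares the observed number of group-shared substitutions with the ILS
#' expectation over `n_var` tested sites. Two methods:
#' `"dataset-grouping"` partitions a stream of simulated per-site match
#' indicators into datasets of `n_var` draws and reports the fraction of
#' datasets with at least the observed count (the resampled-dataset
#' formulation); `"binomial-tail"` reports `Pr(X >= observed)` for
#' `X ~ Binomial(n_var, p_hat)` — the same quantity computed exactly given
#' `p_hat`.
#'
#' @param observed Observed count (genes or sites) of shared substitutions.
#' @param n_var Number of variable amino-acid sites tested.
#' @param p_hat_or_patterns An `ils_pattern_prob`, a bare probability, or
#'   (for dataset-grouping) a 0/1 indicator vector of simulated per-site
#'   matches.
#' @param method `"binomial-tail"` or `"dataset-grouping"`.
#' @param n_datasets Simulated datasets for dataset-grouping when only a
#'   probability is supplied (default 10000).
#' @param seed Optional seed for dataset-grouping resampling.
#' @return An object of class `phylogwas_result`: list with `p_value`,
#'   `method`, `observed`, `n_var`, `p_hat`, `expected` (= n_var * p_hat),
#'   `n_datasets`.
#' @export
phylogwas_pvalue <- function(observed, n_var, p_hat_or_patterns,
                             method = c("binomial-tail", "dataset-grouping"),
                             n_datasets = 10000, seed = NULL) {
  method <- match.arg(method)
  if (n_var < 1) stop("n_var must be positive")
  if (observed < 0 || observed > n_var)
    stop("observed must lie in [0, n_var]")
  x <- p_hat_or_patterns
  indicators <- NULL
  if (inherits(x, "ils_pattern_prob")) {
    p_hat <- x$p_hat
    indicators <- x$indicators
  } else if (is.numeric(x) && length(x) == 1L) {
    p_hat <- x
  } else {
    indicators <- as.integer(x)
    p_hat <- mean(indicators)
  }
  if (method == "binomial-tail") {
    p <- if (observed == 0) 1
         else pbinom(observed - 1, n_var, p_hat, lower.tail = FALSE)
    n_datasets <- NA_integer_
  } else {
    if (!is.null(seed)) set.seed(seed)
    counts <- if (!is.null(indicators)) {
      n_full <- floor(length(indicators) / n_var)
      if (n_full < 1)
        stop("indicator stream shorter than one dataset of n_var sites")
      n_datasets <- n_full
      colSums(matrix(indicators[seq_len(n_full * n_var)], nrow = n_var))
    } else {
      rbinom(n_datasets, n_var, p_hat)
    }
    p <- mean(counts >= observed)
  }
  structure(list(p_value = p, method = method, observed = observed,
                 n_var = n_var, p_hat = p_hat, expected = n_var * p_hat,
                 n_datasets = n_datasets),
            class = "phylogwas_result")
}

#' @export
print.phylogwas_result <- function(x, ...) {
  cat(sprintf(paste0("PhyloGWAS excess test: observed %d, expected %.3g ",
                     "(n_var = %d), P = %.3g [%s]\n"),
              x$observed, x$expected, x$n_var, x$p_value, x$method))
  invisible(x)
}
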