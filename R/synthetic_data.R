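# Synthetic radiation-scale data: ILS-laden gene trees, codon alignments
# with background synonymous/nonsynonymous variation, injected
# group-specific nonsynonymous sites, and per-taxon missingness — so every
# analysis stage is testable without external data.

# default species tree: a rapid radiation of 8 ingroup species plus an
# outgroup, short internal branches (0.5-1 coalescent units on the 2*Ne
# scale) giving substantial gene-tree discordance; ultrametric, height 4 CU
.DEFAULT_SYNTH_TREE <- paste0(
  "(((((sp1:0.5,sp2:0.5):0.5,(sp3:0.5,sp4:0.5):0.5):1,",
  "(sp5:1.5,sp6:1.5):0.5):1,(sp7:2,sp8:2):1):1,out:4);")

.ACGT <- c("A", "C", "G", "T")
.IUPAC2 <- c(AC = "M", AG = "R", AT = "W", CG = "S", CT = "Y", GT = "K")

#' Configuration for the synthetic-data generator
#'
#' The defaults emulate a rapid radiation with pervasive ILS: 8 ingroup
#' species plus an outgroup on an ultrametric species tree with internal
#' branches of 0.5-1 coalescent units (2*Ne scale), a focal phenotype group
#' of three species that is non-monophyletic (sp3, sister to focal sp4,
#' sits inside the focal clade's neighbourhood), two sampled chromosomes
#' per species with the species sequence taken as the fixed-nucleotide
#' consensus, and light per-taxon missingness.
#'
#' @param species_tree Newick string or [species_tree_cu()]; default: the
#'   built-in 9-taxon radiation in COAL units.
#' @param focal Focal species (default sp1, sp2, sp3 — non-monophyletic).
#' @param required_present Species required at counted sites (default sp4,
#'   the focal group's closest relative).
#' @param outgroup Outgroup species label (default "out").
#' @param n_genes Number of genes (default 200).
#' @param codons_per_gene Codons per gene (default 50).
#' @param mut_rate Background nucleotide mutation rate per site per
#'   coalescent unit (2*Ne scale; default 0.003).
#' @param n_inject Number of injected group-specific nonsynonymous sites
#'   (default 0; they are placed in distinct genes when possible).
#' @param miss_rate Per-species per-codon missingness probability
#'   (default 0.05).
#' @param chroms_per_species Chromosomes simulated per species (default 2,
#'   diploid; the species sequence is their fixed-site consensus).
#' @param seed Integer seed; the whole dataset is a deterministic function
#'   of the config.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(species_tree = NULL, focal = c("sp1", "sp2", "sp3"),
                         required_present = "sp4", outgroup = "out",
                         n_genes = 200, codons_per_gene = 50,
                         mut_rate = 0.003, n_inject = 0, miss_rate = 0.05,
                         chroms_per_species = 2L, seed = 1L) {
  if (is.null(species_tree))
    species_tree <- species_tree_cu(.DEFAULT_SYNTH_TREE,
                                    unit_convention("COAL"))
  if (is.character(species_tree))
    species_tree <- species_tree_cu(species_tree, unit_convention("COAL"))
  stopifnot(inherits(species_tree, "species_tree_cu"))
  tips <- species_tree$tree$tip.label
  stopifnot(all(focal %in% tips), all(required_present %in% tips))
  if (length(focal) >= length(setdiff(tips, outgroup)))
    stop("focal group must not cover all ingroup species")
  if (mut_rate < 0 || mut_rate > 1 || miss_rate < 0 || miss_rate > 1)
    stop("rates must lie in [0, 1]")
  if (n_inject > n_genes * codons_per_gene)
    stop("more injected sites than codon sites")
  structure(list(species_tree = species_tree, focal = focal,
                 required_present = required_present, outgroup = outgroup,
                 n_genes = as.integer(n_genes),
                 codons_per_gene = as.integer(codons_per_gene),
                 mut_rate = mut_rate, n_inject = as.integer(n_inject),
                 miss_rate = miss_rate,
                 chroms_per_species = as.integer(chroms_per_species),
                 seed = as.integer(seed)),
            class = "synth_config")
}

#' Generate a synthetic codon-alignment data set under the MSC
#'
#' Per gene: a gene tree is drawn under the multispecies coalescent;
#' a random ancestral CDS (stop-free) evolves along it by
#' Poisson-distributed single-nucleotide mutations placed on branches with
#' probability proportional to branch length (Jukes-Cantor-like, with
#' stop codons avoided by redrawing the mutated base); the species-level
#' sequence is the fixed-nucleotide consensus of the species' chromosomes
#' (polymorphic sites become missing). Injected group-specific sites then
#' overwrite one codon so that exactly the focal species share a
#' nonsynonymous state; finally, per-species missingness masks whole
#' codons. Everything is a deterministic function of `config$seed`.
#'
#' @param config A [synth_config()].
#' @return List with `alignments` (codon-alignment set, species level),
#'   `gene_trees` (a [gene_tree_set()] of chromosome-level trees),
#'   `species_tree`, `truth` (data.frame of injected sites: gene, codon,
#'   focal_aa, other_aa, masked_species), and `config`.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  code <- .genetic_code()
  stops <- names(code)[code == "*"]
  ok_codons <- names(code)[code != "*"]
  sp <- .st_prep(config$species_tree, config$chroms_per_species,
                 allow_inf = FALSE)
  n_sites <- 3L * config$codons_per_gene
  n_ch <- length(sp$chrom)
  mu_ms <- config$mut_rate * 2  # per site per ms unit (1 ms unit = 2 CU)
  raw <- cpp_sim_trees(sp$parent, sp$height, sp$order, sp$n_tip, sp$samples,
                       config$n_genes)
  alignments <- vector("list", config$n_genes)
  trees <- vector("list", config$n_genes)
  gene_ids <- sprintf("gene%04d", seq_len(config$n_genes))
  sp_rows <- split(seq_len(n_ch), sp$chrom_species)[unique(sp$chrom_species)]
  for (g in seq_len(config$n_genes)) {
    m <- raw[[g]]
    trees[[g]] <- .merges_to_phylo(m, sp$chrom)
    # node bookkeeping (0-based ids from the simulator)
    times <- c(rep(0, n_ch), m$time)
    parentg <- integer(2L * n_ch - 1L)
    desc <- c(lapply(seq_len(n_ch), identity), vector("list", n_ch - 1L))
    for (i in seq_len(n_ch - 1L)) {
      node <- n_ch + i
      kids <- c(m$left[i], m$right[i]) + 1L
      parentg[kids] <- node
      desc[[node]] <- c(desc[[kids[1]]], desc[[kids[2]]])
    }
    blen <- times[parentg[seq_len(2L * n_ch - 2L)]] -
      times[seq_len(2L * n_ch - 2L)]
    total <- sum(blen)
    anc <- unlist(strsplit(sample(ok_codons, config$codons_per_gene,
                                  replace = TRUE), ""),
                  use.names = FALSE)
    seqm <- matrix(rep(anc, each = n_ch), nrow = n_ch)
    n_mut <- rpois(1, mu_ms * total * n_sites)
    if (n_mut > 0) {
      br <- sample.int(2L * n_ch - 2L, n_mut, replace = TRUE, prob = blen)
      site <- sample.int(n_sites, n_mut, replace = TRUE)
      mtime <- times[br] + runif(n_mut) * blen[br]
      ord <- order(mtime, decreasing = TRUE)  # oldest first
      for (k in ord) {
        tips_k <- desc[[br[k]]]
        s <- site[k]
        ci <- (s - 1L) %/% 3L
        cpos <- s - 3L * ci
        codon_now <- seqm[tips_k[1], (3L * ci + 1L):(3L * ci + 3L)]
        cur <- codon_now[cpos]
        for (b in sample(setdiff(.ACGT, cur))) {
          cand <- codon_now
          cand[cpos] <- b
          if (!(paste(cand, collapse = "") %in% stops)) {
            seqm[tips_k, s] <- b
            break
          }
        }
      }
    }
    # fixed-nucleotide species consensus
    cons <- vapply(sp_rows, function(rows) {
      if (length(rows) == 1L) return(paste(seqm[rows, ], collapse = ""))
      agree <- seqm[rows[1], ]
      for (r in rows[-1]) agree[agree != seqm[r, ]] <- "N"
      paste(agree, collapse = "")
    }, character(1))
    alignments[[g]] <- cons
  }
  names(alignments) <- gene_ids
  # injected group-specific nonsynonymous sites
  truth <- data.frame(gene = character(0), codon = integer(0),
                      focal_aa = character(0), other_aa = character(0),
                      masked_species = character(0), stringsAsFactors = FALSE)
  if (config$n_inject > 0) {
    inj_genes <- if (config$n_inject <= config$n_genes)
      sample(gene_ids, config$n_inject)
    else sample(gene_ids, config$n_inject, replace = TRUE)
    inj_codon <- sample.int(config$codons_per_gene, config$n_inject,
                            replace = TRUE)
    for (i in seq_len(config$n_inject)) {
      pair <- .draw_nonsyn_pair(code, ok_codons)
      g <- inj_genes[i]
      ci <- inj_codon[i]
      rng <- (3L * (ci - 1L) + 1L):(3L * ci)
      aln <- alignments[[g]]
      focal_sp <- names(aln) %in% config$focal
      for (s in seq_along(aln)) {
        codon <- if (focal_sp[s]) pair$focal else pair$other
        substr(aln[s], rng[1], rng[3]) <- codon
      }
      alignments[[g]] <- aln
      truth <- rbind(truth, data.frame(
        gene = g, codon = ci, focal_aa = unname(code[pair$focal]),
        other_aa = unname(code[pair$other]), masked_species = "",
        stringsAsFactors = FALSE))
    }
  }
  # per-taxon codon missingness
  if (config$miss_rate > 0) {
    for (g in seq_along(alignments)) {
      aln <- alignments[[g]]
      for (s in seq_along(aln)) {
        hit <- which(runif(config$codons_per_gene) < config$miss_rate)
        for (ci in hit)
          substr(aln[s], 3L * (ci - 1L) + 1L, 3L * ci) <- "NNN"
        if (length(hit) && nrow(truth)) {
          m <- truth$gene == names(alignments)[g] & truth$codon %in% hit
          if (any(m))
            truth$masked_species[m] <- ifelse(
              nzchar(truth$masked_species[m]),
              paste(truth$masked_species[m], names(aln)[s], sep = ","),
              names(aln)[s])
        }
      }
      alignments[[g]] <- aln
    }
  }
  gts <- gene_tree_set(trees, gene_id = gene_ids, outgroup = config$outgroup)
  list(alignments = alignments, gene_trees = gts,
       species_tree = config$species_tree, truth = truth, config = config)
}

# a random nonsynonymous codon pair differing at one position, both stop-free
.draw_nonsyn_pair <- function(code, ok_codons) {
  repeat {
    other <- sample(ok_codons, 1)
    pos <- sample.int(3L, 1)
    cur <- substr(other, pos, pos)
    b <- sample(setdiff(.ACGT, cur), 1)
    focal <- other
    substr(focal, pos, pos) <- b
    if (code[focal] != "*" && code[focal] != code[other])
      return(list(focal = focal, other = other))
  }
}

#' Emit per-individual sequences with IUPAC heterozygote codes
#'
#' Expands species-level sequences to `individuals_per_species` copies and
#' converts each site, independently per individual with probability
#' `heterozygosity`, to the two-base IUPAC code pairing the original base
#' with a random other base. [fix_species_sequence()] on the output
#' recovers the species consensus except where a heterozygous or missing
#' call removes the site.
#'
#' @param species_seqs Named character vector (one sequence per species).
#' @param heterozygosity Per-site heterozygote probability in \[0, 1\].
#' @param individuals_per_species Copies per species (>= 1).
#' @param seed Optional integer seed.
#' @return Named list: species -> character vector of individual
#'   sequences.
#' @export
emit_individuals <- function(species_seqs, heterozygosity = 0.01,
                             individuals_per_species = 2L, seed = NULL) {
  stopifnot(heterozygosity >= 0, heterozygosity <= 1)
  if (individuals_per_species < 1)
    stop("individuals_per_species must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  lapply(species_seqs, function(s) {
    vapply(seq_len(individuals_per_species), function(i) {
      chars <- strsplit(toupper(s), "")[[1]]
      base <- chars %in% .ACGT
      het <- base & runif(length(chars)) < heterozygosity
      if (any(het)) {
        chars[het] <- vapply(chars[het], function(b) {
          o <- sample(setdiff(.ACGT, b), 1)
          .IUPAC2[paste(sort(c(b, o)), collapse = "")]
        }, character(1))
      }
      paste(chars, collapse = "")
    }, character(1))
  })
}

#' Write a generated dataset to disk
#'
#' FASTA per gene, chromosome-level gene trees and the species tree as
#' newick, the injected-site truth table as TSV, and the configuration as
#' JSON (provenance).
#'
#' @param dataset Output of [generate_dataset()].
#' @param dir Output directory (created if absent).
#' @export
write_dataset <- function(dataset, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_codon_alignments(dataset$alignments, file.path(dir, "alignments"))
  write_newick_trees(structure(dataset$gene_trees$trees,
                               class = "multiPhylo"),
                     file.path(dir, "gene_trees.nwk"))
  ape::write.tree(dataset$species_tree$tree,
                  file.path(dir, "species_tree.nwk"))
  write.table(dataset$truth, file.path(dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  cfg <- dataset$config
  cfg$species_tree <- write_newick(cfg$species_tree$tree)
  jsonlite::write_json(unclass(cfg), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
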