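# Orchestration layer: end-to-end analysis commands producing
# machine-readable JSON/TSV reports with a provenance block (package
# version, config hash, seeds, input checksums). These functions are the
# pipeline interface; each wraps one analysis stage.

.provenance <- function(config, seed, inputs = character()) {
  sums <- if (length(inputs)) as.list(tools::md5sum(inputs)) else list()
  list(tool = "radphylo",
       version = as.character(utils::packageVersion("radphylo")),
       config_hash = rlang::hash(config),
       seed = seed,
       input_md5 = sums)
}

.write_report <- function(report, file) {
  if (!is.null(file)) {
    jsonlite::write_json(report, file, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, force = TRUE)
  }
  invisible(report)
}

#' Run the organellar introgression test and write a JSON report
#'
#' Wraps [clade_frequency_test()] with organellar scaling on; the report
#' records the P value, the per-replicate clade-frequency distribution, the
#' unit-conversion audit trail and provenance.
#'
#' @param species_tree A [species_tree_cu()] or newick file path (SNAQ
#'   units assumed for files).
#' @param pair Two species whose observed clustering is under test.
#' @param n_reps,trees_per_rep Simulation size (defaults 100 x 100000).
#' @param seed Integer seed (required for a stochastic command).
#' @param out Optional JSON output path.
#' @return The report, invisibly a list.
#' @export
run_mito_test <- function(species_tree, pair, n_reps = 100,
                          trees_per_rep = 100000, seed = 1, out = NULL) {
  input <- character()
  if (is.character(species_tree) && file.exists(species_tree)) {
    input <- species_tree
    species_tree <- species_tree_cu(readLines(species_tree, warn = FALSE)[1])
  }
  res <- clade_frequency_test(species_tree, pair, organelle = TRUE,
                              n_reps = n_reps, trees_per_rep = trees_per_rep,
                              seed = seed)
  cfg <- list(pair = pair, n_reps = n_reps, trees_per_rep = trees_per_rep,
              convention = species_tree$convention$name)
  report <- list(
    analysis = "organellar clade-frequency ILS test",
    pair = res$pair,
    p_value = res$p_value,
    replicate_frequencies = res$freq,
    n_reps = n_reps, trees_per_rep = trees_per_rep,
    unit_conversion = paste0(species_tree$convention$name,
                             " -> MS with organellar Ne scaling (x",
                             1 / species_tree$convention$organelle_ne_fraction,
                             " then convention change)"),
    interpretation = if (res$p_value < 0.05)
      "clustering unlikely under ILS alone (introgression favoured)"
    else "clustering compatible with ILS alone",
    provenance = .provenance(cfg, seed, input))
  .write_report(report, out)
}

#' Concordance-factor goodness-of-fit report
#'
#' Observed CFs are computed from the gene trees for each supplied quartet,
#' expected CFs from the species tree under the MSC, and the two compared
#' by chi-square ([cf_goodness_of_fit()]).
#'
#' @param gene_trees `multiPhylo`, [gene_tree_set()], or newick file path.
#' @param species_tree A [species_tree_cu()].
#' @param quartets List of 4-species character vectors; default: all
#'   quartets of the species tree (use with small trees only).
#' @param tip_map Optional tip -> species map.
#' @param out Optional JSON output path.
#' @return The report list, invisibly.
#' @export
run_cf_test <- function(gene_trees, species_tree, quartets = NULL,
                        tip_map = NULL, out = NULL) {
  input <- character()
  if (is.character(gene_trees)) {
    input <- gene_trees
    gene_trees <- read_newick_trees(gene_trees)
  }
  if (inherits(gene_trees, "gene_tree_set")) {
    if (is.null(tip_map)) tip_map <- gene_trees$tip_map
    gene_trees <- gene_trees$trees
  }
  if (is.null(quartets)) {
    tips <- species_tree$tree$tip.label
    quartets <- combn(tips, 4, simplify = FALSE)
  }
  obs <- lapply(quartets, function(q)
    observed_quartet_cfs(gene_trees, q, tip_map))
  exp <- lapply(quartets, function(q) expected_quartet_cfs(species_tree, q))
  fit <- cf_goodness_of_fit(obs, exp)
  report <- list(
    analysis = "quartet concordance-factor fit to the MSC",
    n_quartets = length(quartets),
    statistic = fit$statistic, df = fit$df, p_value = fit$p_value,
    interpretation = if (fit$p_value > 0.05)
      "discordance consistent with ILS over the species tree"
    else "discordance exceeds the ILS expectation",
    caveat = fit$caveat,
    observed = lapply(obs, function(x)
      list(quartet = x$species, cf = x$cf, n = x$n)),
    expected = lapply(exp, function(x)
      list(quartet = x$species, cf = x$cf)),
    provenance = .provenance(list(n_quartets = length(quartets)), NA, input))
  .write_report(report, out)
}

#' Full PhyloGWAS analysis: scan, simulated null, P value
#'
#' Runs [find_shared_substitutions()] on the alignments, estimates the
#' single-mutation ILS pattern probability with the observed missingness
#' weighting ([estimate_ils_pattern_probability()]), and reports the
#' excess P value ([phylogwas_pvalue()]). Site-level results can be
#' written as TSV alongside the JSON summary.
#'
#' @param alignments Codon-alignment set (or directory of FASTA files).
#' @param species_tree A [species_tree_cu()].
#' @param group A [group_spec()].
#' @param n_sims Simulated single-mutation genes for the null
#'   (default 1e6).
#' @param method P-value method, see [phylogwas_pvalue()].
#' @param count Observed statistic: `"sites"` (default; the site count is
#'   on the same scale as the per-site null, so its P value is calibrated)
#'   or `"genes"` (shared sites cluster on favourable gene trees, so the
#'   gene count runs below the site-level expectation and its P value is
#'   conservative).
#' @param seed Integer seed.
#' @param out Optional JSON output path.
#' @param site_tsv Optional site-level TSV output path.
#' @return The report list, invisibly.
#' @export
run_phylogwas <- function(alignments, species_tree, group, n_sims = 1e6,
                          method = "binomial-tail",
                          count = c("sites", "genes"), seed = 1, out = NULL,
                          site_tsv = NULL) {
  count <- match.arg(count)
  input <- character()
  if (is.character(alignments)) {
    alignments <- read_codon_alignments(alignments)
  }
  scan <- find_shared_substitutions(alignments, group)
  pp <- estimate_ils_pattern_probability(
    species_tree, group, scan$missing_configs, n_sims = n_sims, seed = seed,
    keep_indicators = identical(method, "dataset-grouping"))
  observed <- if (count == "sites") scan$s_sites else scan$s_genes
  pv <- phylogwas_pvalue(observed, max(scan$n_var, 1L), pp,
                         method = method)
  if (!is.null(site_tsv))
    write.table(scan$sites, site_tsv, sep = "\t", quote = FALSE,
                row.names = FALSE)
  cfg <- list(focal = group$focal, required = group$required_present,
              n_sims = n_sims, method = method)
  report <- list(
    analysis = "PhyloGWAS shared nonsynonymous substitution excess",
    focal_group = group$focal,
    s_genes = scan$s_genes, s_sites = scan$s_sites, n_var = scan$n_var,
    observed_statistic = count,
    p_hat = pp$p_hat, p_hat_se = pp$se, n_sims = n_sims,
    expected_shared = pp$p_hat * scan$n_var,
    p_value = pv$p_value, method = pv$method,
    missing_configs = scan$missing_configs,
    provenance = .provenance(cfg, seed, input))
  .write_report(report, out)
}

#' ED/EDGE scoring report
#'
#' Computes evolutionary distinctness from a dated tree, joins IUCN threat
#' categories and writes the EDGE table as TSV.
#'
#' @param tree A [time_tree()], `phylo`, or newick file path (My units).
#' @param iucn Data.frame (species, iucn_category), named vector, or TSV
#'   path with those columns.
#' @param out Optional TSV output path.
#' @return The EDGE table data.frame, invisibly.
#' @export
run_edge_scoring <- function(tree, iucn, out = NULL) {
  if (is.character(tree) && file.exists(tree))
    tree <- parse_newick(readLines(tree, warn = FALSE)[1])
  if (is.character(iucn) && length(iucn) == 1L && file.exists(iucn))
    iucn <- read.table(iucn, header = TRUE, sep = "\t",
                       stringsAsFactors = FALSE)
  tab <- edge_table(tree, iucn)
  if (!is.null(out))
    write.table(tab, out, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(tab)
}
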