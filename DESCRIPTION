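Package: radphylo
Title: Coalescent Null Models for Discordance, Parallel Selection and
    Evolutionary Distinctness in Rapid Radiations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Comparative-phylogenomic toolkit for rapid radiations with
    pervasive incomplete lineage sorting (ILS), built around a multispecies
    coalescent (MSC) simulator over a species tree in coalescent units.
    Provides a clade-frequency test for organellar introgression against the
    ILS null, observed and expected quartet concordance factors with a
    chi-squared goodness-of-fit, a phylogenetic genome-wide association scan
    (PhyloGWAS) for nonsynonymous substitutions shared by non-monophyletic
    phenotype groups with a simulated single-mutation ILS null and
    missing-taxa weighting, deterministic transcriptome data-preparation
    filters (alignment occupancy, outgroup monophyly, support-based
    transcript selection, supermatrix concatenation, fourfold-degenerate
    site extraction), evolutionary-distinctness (ED) and EDGE conservation
    scoring, and a synthetic-data generator that emulates the statistical
    structure of a radiation-scale transcriptome data set.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    Biostrings,
    jsonlite,
    Rcpp,
    rlang,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    picante,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
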