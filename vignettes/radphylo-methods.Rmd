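---
title: "Coalescent null models for rapid radiations: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coalescent null models for rapid radiations: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Rapid radiations — a handful of species splitting within a few million
years — leave a characteristic genomic signature: gene trees disagree with
the species tree at many loci because ancestral polymorphism persists
across short internodes (incomplete lineage sorting, ILS). Every inference
about such a group must therefore be made *against* an ILS null, not
against a naive expectation of gene-tree concordance. `radphylo`
implements that programme for three questions, with *Thunnus* tunas (eight
closely related species plus a skipjack-like outgroup) as the motivating
system:

1. **Is an observed organellar sister-pairing introgression or just
   ILS?** (clade-frequency test)
2. **Does nuclear gene-tree discordance exceed what the multispecies
   coalescent predicts?** (quartet concordance factors, chi-squared fit)
3. **Do species sharing a phenotype — but not a clade — share more
   nonsynonymous substitutions than ILS alone would give them?**
   (PhyloGWAS excess test)

A fourth, deterministic component scores species for conservation
priority (ED/EDGE), and a data-preparation layer reproduces the filtering
rules used on transcriptome-derived alignments.

# The simulator and its unit conventions

All nulls rest on a censored multispecies-coalescent simulator over a
rooted species tree whose branch lengths are coalescent units. Within a
branch, `k` gene lineages coalesce pairwise as a Kingman coalescent;
survivors of a branch enter its parent; the root population coalesces to
one lineage. The C++ core works on the *ms* time scale (one unit = 4Ne
generations, so a pair coalesces at rate 2), and everything is converted
on entry.

Coalescent-unit conventions differ across the literature, so the package
makes them explicit objects (`unit_convention()`):

* `SNAQ`: 1 x Ne generations per unit — the definition stated with the
  SNaQ-derived trees this package consumes. Note that the usual
  network-literature definition is 2Ne; the stated factor is the default
  here, and the multiplier is a configurable field precisely because this
  gloss is contested.
* `COAL`: 2 x Ne — the scale on which the two minor quartet topologies
  each have expected concordance factor `exp(-t)/3`.
* `MS`: 4 x Ne — the simulator scale.

Organellar loci get a separate knob: with an organelle Ne of one quarter
of the nuclear Ne (mitochondria in a diploid), branch lengths are
multiplied by 4 *before* the convention change. For a SNaQ-unit tree
converted to the ms scale, the x4 and the /4 cancel exactly — the package
performs the conversion literally so the audit trail is visible, and a
test asserts bitwise identity.

Branch lengths may be flagged infinite (forced monophyly). Topology-only
operations map `Inf` to 500 ms units, where the probability that a lineage
pair fails to coalesce is `exp(-1000)` — exactly 0 in double precision.
Site-pattern simulation refuses non-finite lengths, since mutation
placement weights branches by length.

**Determinism.** The C++ core draws from R's global RNG stream: one
`set.seed()` reproduces every gene tree, site pattern and generated
dataset byte-for-byte. There are no per-gene substreams; the simulator is
single-threaded, and a single stream keeps the contract simple.

# Discordance analyses

**Clade-frequency test.** `clade_frequency_test()` simulates (by default)
100 replicates of 100,000 gene trees, one chromosome per species, and
records per replicate the fraction in which the queried pair forms an
exclusive clade in the rooted gene tree; the P value is the mean fraction.
"Clustered" is operationalised as exclusive-clade formation — the
behaviour observed in an organellar tree where two species appear as
sisters among species-level lineages. The test's two analytic limits
(P = 1 for an infinite stem; P = 1/3 for a three-species star) are part of
the test suite.

**Concordance factors.** Observed CFs (`observed_quartet_cfs()`) follow a
two-step tip-based scheme: within each gene tree, every combination of one
tip per quartet species is reduced to its induced unrooted quartet;
per-gene topology proportions (over resolved combinations) are then
averaged with equal weight across genes. Unresolved combinations
(polytomies) are excluded from the gene's denominator. Expected CFs
(`expected_quartet_cfs()`) use the closed form with `t` the total internal
path length of the pruned four-taxon tree on the `COAL` scale — exact for
arbitrary placements of the quartet on the species tree, because a quartet
is discordant only when both cherry lineage-pairs fail to coalesce below
their join.

**Goodness of fit.** `cf_goodness_of_fit()` compares counts `n * CF` by
Pearson chi-square, 2 df per quartet, summed over quartets. The paper
trail behind this test names the TICR procedure but describes only the
chi-squared comparison; the package implements the described test, not the
full TICR outlier machinery. Two caveats are attached to the output: the
df/pooling convention (sum over quartets) is a declared choice, and
quartets drawn from a shared gene-tree set are not independent, so the
global P value is approximate. A calibration test confirms the rejection
rate under the null stays near nominal for a single quartet.

# The PhyloGWAS scan

`find_shared_substitutions()` scans species-level codon alignments for
sites at which all focal species share one amino acid and every
non-missing non-focal species in the contrast set carries the other.
Site filters, applied jointly (they commute):

* at most **2 distinct amino-acid states** among non-missing species —
  more states suggest repeated mutation rather than sorting of one
  ancestral variant;
* at most **2 missing taxa**; codons containing gaps, `N` or IUPAC
  ambiguity codes count as missing for that species;
* every **required species** present (the focal species are always
  required; by default the focal group's closest relative is too, so that
  the contrast is anchored).

`n_var` — the excess test's denominator — counts retained,
required-complete sites with at least two amino-acid states. Sites
removed by the >2-state filter are *not* in `n_var` (the alternative,
counting them, is noted as a sensitivity question). The missingness
configurations of the `n_var` sites are tabulated as exact taxon subsets,
not just counts: subset weighting is strictly more faithful to the match
condition than marginal count weighting, which remains available by
collapsing the table.

**The null.** `estimate_ils_pattern_probability()` simulates
single-mutation genes (infinite sites, one segregating site, mutation on a
branch chosen proportionally to length) with two chromosomes per species
(diploid), and asks how often the mutation induces a fixed amino-acid-like
difference separating the focal group. Two design decisions matter for
calibration, and both were reached by measuring miscalibration on
synthetic null data:

1. **Condition on testability.** A simulated site enters the reported
   probability's denominator only if it is *testable*: every non-ignored
   species fixed (within-species polymorphism becomes missing data under
   the fixed-nucleotide consensus) and the site segregating between
   species. This matches the scale of `n_var`, which also counts only
   such sites. Without conditioning, roughly half the simulated mutations
   sit in the denominator while being invisible to the scan, the null
   probability is deflated about two-fold, and the type-I error at
   alpha = 0.05 is ~0.36. With conditioning, per-configuration match
   rates in synthetic null data agree with the simulated probabilities to
   three decimals.
2. **Count sites, not genes, by default.** Qualifying sites cluster on
   favourable gene trees: one gene tree with a long focal-split branch
   can make several codons qualify at once, so the gene count runs ~13%
   below the site count while the null is site-scaled. The site count is
   therefore the calibrated default statistic in `run_phylogwas()`; the
   gene count — the headline quantity in comparative studies — is always
   reported alongside and can be selected, with the understanding that
   its P value is conservative.

Polarity defaults to `"either"` (the group may be ancestral or derived):
amino-acid fixed differences carry no polarization. Species outside the
ingroup contrast (the outgroup) must be fixed for a site to be testable
but may take either state, mirroring the scan. The default null size is
10^6 simulated genes — at the package's problem sizes this puts the
Monte-Carlo SE of the pattern probability near 3% of its value; scale
`n_sims` up towards 10^8 for publication-grade tail estimates.

`phylogwas_pvalue()` offers the dataset-grouping formulation (partition a
simulated per-site match stream into datasets of `n_var` draws; P = the
fraction with at least the observed count) and the binomial tail
`Pr(X >= observed)`, `X ~ Binomial(n_var, p-hat)` — the same quantity
computed exactly; a test confirms they agree within Monte-Carlo error on a
shared stream.

# Data preparation

The deterministic filter chain mirrors standard transcriptome practice:
columns with <10% occupancy are removed first, then sequences with >50%
gaps, then alignments with <4 species are discarded (this order follows
the order in which the rules are stated; occupancy counts ambiguity codes
as occupied). Gene trees whose outgroup tips are not an exclusive clade
are dropped — trees with zero or one outgroup tip pass vacuously, a
declared convention. Per transcript cluster, only the tree with the most
nodes of SH-like support above 10 survives (ties broken by lexicographic
gene id; clusters whose best tree has no such node vanish). Supermatrix
concatenation fills species-absent genes with `N` and emits a RAxML-style
partition table. Fourfold-degenerate extraction takes third positions of
codons whose first two bases place *every non-missing species* in a
fourfold family — strict per-species checking avoids nonsynonymous
contamination; missing species are ignored at that column.

# ED and EDGE

`evolutionary_distinctness()` uses fair proportion — each branch divided
equally among its descendant tips — so per-tip scores sum to the total
tree length (a conservation test asserts this to 1e-6 on random trees).
Equal splits is available behind a flag; it does not conserve total
length. Fair proportion is the method whose output is internally
consistent with the published per-species scores this package's acceptance
checks recompute. `edge_score()` is `ln(1 + ED) + GE * ln(2)` with GE the
IUCN category (LC = 0 through CR = 4); data-deficient species get an
undefined (NA) EDGE, never 0 — a missing threat assessment is a data gap,
not a low priority. ED acceptance checks operate at the formula level
(published ED values as inputs), since the exact tree (posterior mean vs
consensus) behind published ED values is not recoverable.

# The synthetic-data generator

`generate_dataset()` emulates the statistical structure the analyses
assume: a 9-taxon ultrametric species tree (8 ingroup + outgroup) with
internal branches of 0.5–1 coalescent units — short enough that minor
quartet topologies run near 20% each, the regime of a rapid radiation; a
non-monophyletic focal group of three species whose closest relative is
required at tested sites; two chromosomes per species with the species
sequence taken as the fixed-nucleotide consensus (polymorphic sites
become missing, as in real genotype-derived data); Jukes–Cantor-like
background mutation at 0.003 per site per coalescent unit (a value that
yields a few variable amino-acid sites per 50-codon gene, matching
transcriptome-scale information density); optional injected
group-specific nonsynonymous sites (the parallel-selection signal, with a
truth table for exact bookkeeping); and 5% per-species per-codon
missingness. Stop codons are avoided by redrawing the mutated base at the
affected codon only.

What it does **not** emulate: assembly and mapping artefacts, paralogy,
selection on background variation, recombination within genes,
hybridization. Passing tests on this generator therefore demonstrate
statistical correctness of the methods under the MSC — not robustness to
upstream bioinformatic error.

# Numerical choices and problem sizes

* Expected-CF continuity floor: expected CFs of 0 are floored at 1e-8
  before Pearson counts (configurable).
* Tie-breaks are deterministic everywhere (lexicographic gene id in
  transcript selection).
* The type-I-error experiment uses 200 null datasets of 700 genes x 50
  codons: this puts the expected null site count near 6, where the
  discrete binomial tail has genuine resolution at alpha = 0.05 — at
  smaller expected counts the achievable rejection rate oscillates below
  2% purely from discreteness. The recovery experiment uses 70 genes so
  that the expected null count stays below one, the regime in which a
  ten-gene injected signal must be decisive.
* Simulation-based checks run at 10^4–10^6 draws with 3-standard-error
  tolerances derived from the quantity under test.

# Limitations

* The SNaQ-unit definition follows its stated gloss (generations/Ne); if
  a tree uses the 2Ne convention, construct it with `COAL` or set
  `ne_multiplier` explicitly.
* The chi-squared CF fit ignores between-quartet dependence; treat the
  global P value as descriptive when many overlapping quartets are
  pooled.
* The PhyloGWAS null models a single mutation per gene; data generated
  with finite mutation rates lose a small fraction of patterns to second
  hits (the effect cancels between numerator and denominator to first
  order, and measured calibration is near-nominal).
* Networks (hybridization edges) are out of scope: the null is always a
  tree.
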