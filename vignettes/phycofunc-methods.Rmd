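---
title: "Methods: genome-centric metabolic profiling with phycofunc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genome-centric metabolic profiling with phycofunc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phycofunc)
```

## The analysis this package implements

Genome-centric metagenomics reconstructs draft genomes (metagenome-assembled
genomes, MAGs) from community sequencing and asks, organism by organism, who
can do what. For algal-surface ("phycosphere") communities the questions of
interest are the metabolic exchanges with the host: who can fix carbon,
reduce nitrate, degrade taurine, hydrolyse organic phosphorus, synthesise or
consume cobalamin (vitamin B12), produce the auxin IAA, or degrade the
ethylene precursor ACC. `phycofunc` covers the downstream, annotation-level
part of such a study: it starts from per-genome KO (KEGG Orthology)
annotation tables, genome quality estimates, a rooted genome tree and
per-sample coverages — all products of standard upstream tools — and
performs quality gating, pathway assignment, phylogenetic-diversity
accounting and abundance summaries.

## Genome quality model

Completeness and contamination are single-copy-marker estimates in percent.
Two sequential gates are applied:

1. **Bin refinement**: completeness > 50 *and* contamination < 10, both
   strict, matching the convention of automated bin-refinement tools.
2. **Tree inclusion**: the scalar score
   $Q = \text{completeness} - 5 \times \text{contamination}$
   must not fall below 40; genomes with $Q < 40$ are removed, so $Q = 40$
   exactly is kept. The factor 5 penalises contamination heavily because
   foreign fragments both inflate apparent gene content and distort marker
   placement in trees.

Scores are kept at full floating precision internally; any rounding (two
decimals, half away from zero, `round_half_away()`) happens only when a
report is emitted.

## Module catalog and assignment rule

A module is an ordered list of reaction *steps*; each step is a disjunction
of *alternatives*, and each alternative is a conjunction of identifiers (a
complex — e.g. the nitrate reductase step of dissimilatory nitrate
reduction is `narG+narH+narI , napA+napB`). *Key clauses* use the same
grammar and name the enzymes whose presence is mandatory for the pathway to
be credible at all (ATP-citrate lyase `aclA+aclB` for the rTCA cycle,
malonyl-CoA reductase `mcr` for the 3-hydroxypropionate bicycle, `ipdC`
for the indole-3-pyruvate route to IAA, ...).

A module is **assigned** to a genome when

* completeness — satisfied steps / total steps — is at least the threshold
  (default 0.6, inclusive: exactly 60% passes), and
* every key clause has at least one alternative fully present.

Design choices worth making explicit:

* **Binary steps.** A step is satisfied or not; a complex missing one
  subunit contributes nothing. Percent-complete rules are only well defined
  over discrete step counts, and partial credit inside a complex would let
  non-functional fragments accumulate towards the threshold.
* **Exact rationals at the threshold.** The comparison is made on step
  counts (`satisfied >= threshold * n_steps`, with a `1e-9` slack against
  binary-float artifacts), never on a rounded percentage, so a 3-of-5
  module can never be lost to a `59.999…` representation.
* **Sets, not counts.** Multi-copy genes are irrelevant; KO sets are
  deduplicated on input.
* **Step-based vs raw KO fraction.** Whether module completeness should be
  computed over the step structure or over the flat identifier list is a
  genuinely open convention; we fix step-based as the default (it respects
  alternatives: a genome with one full alternative of every step is 100%
  complete) and expose `method = "ko_fraction"` for the flat variant.
* Unannotated genes ("hypothetical proteins") are simply absent
  identifiers; there is no special handling.

The shipped catalog (`builtin_catalog()`, 29 modules) encodes the six
prokaryotic carbon-fixation modules, assimilatory sulfate reduction, and
custom entries for nitrate reduction, denitrification, nitrification,
nitrogen fixation, taurine utilisation, sulfite/thiosulfate oxidation,
alkaline phosphatase, the cobalamin economy (aerobic/anaerobic synthesis,
pseudocobalamin remodelling, DMB synthesis, transport, the two methionine
synthases) and the four IAA routes plus ACC deaminase. KEGG distributes no
auxin-biosynthesis module and only a partial cobalamin picture, which is
why these are custom entries. The step decompositions are a curated
reconstruction from published gene lists, not an official KEGG export; the
plain-text format and `parse_catalog()` make it trivial to substitute a
different catalog, and `builtin_aliases()` maps the gene symbols used in
custom modules to K-numbers (matching is exact string after alias
resolution; symbols without a confident K-number stay unmapped).

## Phylogenetic distance and gain

For a rooted tree with branch lengths and a leaf set $S$, we use **rooted
Faith's PD**: the total branch length of the union of root-to-leaf paths of
$S$. Under this convention PD of the full leaf set equals the total branch
length exactly, and the **phylogenetic gain** of an ingroup,
$PG(S) = PD(\text{all}) - PD(\text{all} \setminus S)$, is additive:
$PG(S) + PD(\text{complement}) = PD(\text{full})$ holds identically. The
unrooted variant (minimal subtree spanning $S$ only) is available via
`faith_pd(..., rooted = FALSE)`; tools differ in which convention they use,
and the rooted one was chosen precisely because it makes the
full-tree/outgroup/ingroup/gain table internally consistent.

Percent-PD values are computed from unrounded internal PDs and rounded (2
decimals, half away from zero) only in the emitted column. Recomputing
percentages from already-rounded PD entries of a published table can differ
in the last digit — a known artifact of reporting precision, which is why
`pd_summary()` never rounds intermediates. Zero-length branches are
allowed (a zero-length pendant leaf contributes no gain); negative lengths
are rejected; missing lengths are zeroed with a warning.

## Abundance bookkeeping

* `relative_abundance()` normalises each sample column of a coverage table
  to 100%.
* `cumulative_filter()` implements the heatmap inclusion rule: keep genomes
  whose abundance **summed across samples** exceeds 1% (strictly; exactly
  1.0 is dropped). The sum — not the mean — is the literal reading of
  "cumulative abundance".
* `trait_weighted_abundance()` sums the relative abundance of all genomes
  assigned to at least one module of a trait set, then averages over the
  samples of a site group. Published site-level percentages rarely state
  how replicate samples were aggregated; the unweighted mean is our
  documented choice.
* `community_recovery()` reports binned coverage / total coverage when an
  unbinned remainder is supplied. This is a coverage-fraction proxy for
  marker-gene-based recovery estimates (SingleM-style appraisal), not a
  reimplementation of them.
* `rarefaction_curve()` evaluates the exact hypergeometric expectation
  $E[S_n] = \sum_i \left[ 1 - \binom{N-N_i}{n} \big/ \binom{N}{n} \right]$
  at $n = \text{step}, 2\,\text{step}, \dots, N$ (default step 2000, the
  common plotting increment), using `lchoose` so deep samples do not
  overflow; the final point equals observed richness exactly.

## The synthetic-community generator

Real inputs to this pipeline come from assembly, binning, GTDB-Tk and KO
annotation. To make every stage testable without those, `sim_config()` /
`simulate_community()` generate all inputs with known ground truth:

* **Trait blocks.** Each genome belongs to one of eleven functional guilds
  (`default_trait_assignment()`), and truly carries every identifier of its
  guild's modules. The guilds are chosen so that no guild's complete
  identifier set assigns a module outside its own list — ground truth is
  recoverable exactly at full completeness, which pins down
  sensitivity/specificity expectations.
* **Dropout.** Each true identifier is retained i.i.d. Bernoulli with
  probability completeness/100 — the simplest model consistent with
  "incomplete pathways because of incomplete genomes". It is a documented
  stand-in, not a fit: real gene loss is contig-correlated.
* **Contamination.** `round(contamination/100 × |true set|)` foreign
  identifiers are added, sampled without replacement from a background pool
  disjoint from every trait block, giving contamination a testable
  signature (with contamination 0, no foreign KOs ever appear).
* **Taxonomy.** GTDB-style 7-rank strings (`d__;p__;c__;o__;f__;g__;s__`)
  drawn from lineage templates weighted like a Bacteroidota-dominated
  phycosphere census with a single archaeon.
* **Tree.** Random topology (`ape::rtree`) with Exp(1) branch lengths
  (rate configurable); rooted, binary, strictly positive lengths.
* **Coverage.** Independent lognormal draws (default meanlog 0,
  sdlog 1.5 — right-skewed, as community abundance distributions are),
  six samples named `RZ-A…ND-C` for the default two-site, three-point
  design.
* **Determinism.** One master seed; three sub-seeds are derived from it
  (one each for genomes, tree, coverage), so outputs are bit-identical
  under a fixed seed and changing the number of samples never perturbs the
  simulated genomes.

Defaults (200 genomes, completeness uniform on [50, 100], contamination
uniform on [0, 10]) mirror a post-refinement MAG cohort: every simulated
genome already sits inside the refinement gate, and the quality spread
straddles the tree-inclusion threshold. What the generator deliberately
does **not** emulate: reads, contigs, binning errors, ANI structure,
phylogenetically correlated trait distributions, or covariance between
abundance and taxonomy. Tests passing on these simulations therefore
validate the *bookkeeping* — gating, completeness logic, PD/PG arithmetic,
normalisation — not the upstream inference steps.

## Verification strategy and problem sizes

The test suite cross-checks every non-trivial computation against an
independent route: Faith's PD against a brute-force union of root-to-leaf
edge paths on all subsets of small random trees (and against
`picante::pd(include.root = TRUE)`); module completeness and key gating
against an enumerator over the full cartesian product of per-step
alternatives; the rarefaction expectation against `vegan::rarefy` and
against Monte-Carlo subsampling (10^4 draws, 3-standard-error bound with a
rule-of-three floor for taxa whose exclusion probability is below MC
resolution); assignment monotonicity under KO supersets on 1000 random
module/KO-set pairs; and ground-truth recovery on 200-genome synthetic
communities, where sensitivity and specificity are exactly 1 at full
completeness and mean true-module completeness decreases strictly along a
100/80/60/40% dropout grid. These sizes (50 trees of ≤ 8 leaves for the
exhaustive subset checks, 200-genome communities, 10^4 Monte-Carlo draws)
were chosen as the smallest scales at which the properties are
non-trivially exercised while the whole suite stays fast enough to run on
every change.

## Known limitations

* The shipped catalog is a reconstruction; step granularity affects the
  60% rule, so swapping in an authoritative catalog can change borderline
  assignments.
* `parse_taxonomy()` expects 7-rank GTDB strings; other conventions are
  grouped as `unclassified` rather than guessed.
* The alias table is intentionally partial; unmapped symbols only match
  themselves.
* Trait-weighted abundances inherit the binned fraction of the community:
  they describe the MAG-represented portion, not the whole microbiome.

## Worked session

```{r}
cfg <- sim_config(n_genomes = 60, seed = 11)
sim <- simulate_community(cfg)
rep <- quality_report(sim$genomes)
sum(rep$passed_tree_filter)

mat <- build_matrix(sim$genomes, sim$ko_sets, builtin_catalog())
keep <- rep$genome_id[rep$passed_tree_filter]
pd_summary(sim$tree, ingroup = keep,
           outgroup = setdiff(sim$genomes$genome_id, keep))

ab <- relative_abundance(sim$coverage)
trait_weighted_abundance(ab, mat, c("CUST_IAM", "CUST_TAM"), "RZ")
```
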