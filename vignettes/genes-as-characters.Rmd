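---
title: "Genes as characters: step-matrix parsimony from gene trees"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genes as characters: step-matrix parsimony from gene trees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genechar)
```

## The problem

Phylogenomic datasets contain hundreds to thousands of loci whose individual
gene trees disagree with one another — through incomplete lineage sorting,
hidden paralogy, alignment error, and plain estimation noise.  The standard
remedy, concatenating all sites into one supermatrix, is known to produce
confidently wrong answers: with enough sites, bootstrap support saturates at
100% even when the underlying loci conflict.  Deep, short internodes — the
placement of turtles among reptiles is the canonical example — are exactly
where this failure mode bites.

`genechar` implements the alternative summarized by its name: **each gene is
one character**.  A gene's observed haplotypes (one per taxon) are the
character's states; the gene's own tree, expressed as a matrix of pairwise
transformation costs, is the character-state tree.  A species tree is scored
by generalized (Sankoff) parsimony over all such characters at once, and
uncertainty is measured by resampling genes, not sites.  Because each gene
contributes a bounded, equally scaled amount of signal, no single
fast-evolving locus can dominate, and the bootstrap reflects genuine
among-gene conflict rather than the sheer number of sites.

## From gene tree to character

For a gene tree $g$ with tip set $S_g$ and branch lengths in
substitutions/site, the patristic distance $d_g(i,j)$ is the sum of branch
lengths on the path between tips $i$ and $j$.  The character's cost matrix is

$$
c_g(i,j) \;=\; \operatorname{round}_2\!\left(
  M \cdot \frac{d_g(i,j)}{\max_{k,l} d_g(k,l)} \right),
$$

with the maximum step $M = 10$: the largest pairwise distance in every gene
is pinned to ten and all other steps scaled proportionally, then kept at two
decimal places (which also forces floating-point rather than integer
tree-length evaluation downstream).  Two consequences matter:

* **Equal weighting.** The normalization cancels the gene's overall rate, so
  a global rescaling of a gene's branch lengths leaves its character
  unchanged — this is the operational meaning of weighting all genes
  equally (`build_character()` is tested for exact invariance under
  branch-length multiplication).
* **Long-branch damping.** A single enormous branch (misalignment,
  paralogy, assembly error) absorbs the whole 0–10 scale and crushes every
  other cost toward zero, rendering the gene nearly uninformative rather
  than actively misleading.

Genes whose trees carry no length at all ($d_{\max}=0$) become all-zero
characters, kept but flagged `uninformative`; they cannot affect any score.

Before conversion, gene trees whose **longest branch exceeds 1.5**
substitutions/site are excluded outright (`filter_long_branch()`); such
branches flag data problems rather than evolution.  The comparison is
strict: a longest branch of exactly 1.5 is kept.  The maximum is taken over
the tree's edges as written; re-rooting with `root_on_outgroup()` keeps the
split edge's full length on one side (the new root edge gets length 0), so
root placement never changes the filter outcome.

## Scoring and searching species trees

`character_length(tree, ch)` is the minimum, over assignments of states to
internal nodes, of the summed edge costs — computed by the usual bottom-up
Sankoff dynamic programming on an arbitrary rooting (costs are symmetric, so
the rooting is irrelevant; this is tested).  Internal nodes range over the
character's *observed* states only, matching the step-matrix (USERTYPE)
semantics of PAUP*-style generalized parsimony: no hypothetical intermediate
haplotypes are synthesized.  Taxa missing from a gene enter as standard
missing data (an all-zero leaf cost vector).  `tree_length()` sums weighted
character lengths; `brute_force_length()` re-derives the same quantity by
exhaustive enumeration of internal-state assignments and serves as the test
oracle, alongside an independent cross-check against
`phangorn::parsimony(method = "sankoff")`.

Search is exhaustive up to nine taxa (all unrooted binary topologies;
945 at seven taxa) and heuristic beyond, or on request: seeded random-order
stepwise addition followed by steepest-descent branch swapping with NNI,
SPR (default), or TBR neighborhoods.  SPR is the default because at these
taxon counts its neighborhood already contains every improvement TBR finds
in practice; TBR remains available to mirror the classical search setting.
Score ties are kept at an absolute tolerance of 1e-9 and summarized by
strict consensus.  The gene bootstrap (`bootstrap()`) resamples characters
with replacement to the original count, re-runs the search per replicate
(1000 replicates by default), and credits each split of a replicate's best
trees, fractionally (1/k) under k-way ties so support behaves continuously.

## The simple count method

Independently of parsimony, `tally()` classifies every gene tree by the
clade hypothesis it contains — e.g. a turtle–archosaur clade versus a
turtle–lepidosaur clade — where "contains" means the diagnostic cluster(s)
appear on the outgroup-rooted tree regardless of other relationships.  A
polytopic node certifies nothing: a gene must actually resolve a clade to
support it.  Nested queries (a clade, the clade plus its next neighbor, the
full topology) are counted non-exclusively and are provably monotone
non-increasing.  Genes lacking a queried taxon count as non-supporting and
are logged.

## Association tests over gene categories

`chisq_2x2()` is the uncorrected Pearson test on a 2×2 table
($\sum (O-E)^2/E$, df = 1).  No Yates continuity correction is applied —
with thousands of genes per margin the correction is pointless and changes
the statistic materially (the package pins this with a regression test).
`association_scan()` builds, per gene category, either a
focal-hypothesis-vs-all-others table (functional-category scans) or a table
conditioned on genes supporting one of two named hypotheses
(selection-vs-hypothesis tests), applies a strict "more than five member
genes" size filter, and reports the statistic, p-value, observed and
expected counts.  A Benjamini–Hochberg column is emitted for reference but
is deliberately not used for filtering, matching the procedure the scan
reproduces.  Under planted-null simulations the scan's type-I error is
calibrated at the nominal 5% (tested at ±2%).

## The simulator

`simulate_species_tree()` draws a topology uniformly over labeled unrooted
binary trees (sequential insertion of each taxon onto a uniformly chosen
edge) with exponential branch lengths of mean 0.1 substitutions/site —
typical magnitudes for the vertebrate transcriptome datasets this method
targets.  `simulate_gene_trees()` then emulates the three features of real
gene-tree sets the method must cope with:

* **topological discordance**: with probability `discordance` (default 0.1)
  a gene's topology is perturbed by `topo_moves` random NNI rearrangements
  (default 1).  NNI perturbation is used rather than a multispecies
  coalescent because the method consumes arbitrary gene trees and makes no
  coalescent assumption; NNI gives direct, interpretable control of
  conflict intensity.
* **rate noise**: every branch is multiplied by an independent
  lognormal(0, sd = 0.3) factor — roughly ±35% per-branch rate variation,
  a realistic gene-to-gene spread.
* **artifacts**: a fraction of genes receive one branch inflated to
  `artifact_scale` (≥ 10) times the gene tree's diameter, mimicking the
  over-long branches that the 1.5 filter exists to remove.

All randomness derives from one run seed; per-gene sub-seeds are a fixed
affine hash of the gene index, so outputs are reproducible bit for bit.
What the simulator does *not* emulate: sequence-level estimation error,
missing-taxon patterns, correlated discordance (e.g. introgression blocks),
or branch-length biases of real ML estimation.  Passing recovery tests on
these simulations therefore demonstrates the machinery is correct and
well-calibrated, not that any particular empirical dataset is resolvable.

## Identifiability limits of restricted-state parsimony

One genuine and, to our knowledge, under-appreciated property surfaced by
this package's own validation: with internal states restricted to observed
haplotypes, a haplotype that sits metrically close to a junction of its
gene tree acts as a free Steiner hub.  Routing through it costs the same
under several local arrangements of its neighbors, so NNI-rearranged
species trees can score **exactly** equal on every clean gene — verified
both by brute-force enumeration and by an independent Sankoff
implementation.  About 17% of random 5-taxon gene trees with generic
(uniform 0.1–1) branch lengths, and roughly a quarter of random 7-taxon
species trees with exponential(0.1) lengths, contain such a configuration.
In those cases no amount of concordant data identifies the species tree
uniquely; whichever discordant genes happen to be sampled break the tie.
This is intrinsic to the step-matrix formulation (hypothetical ancestral
haplotypes do not exist as states) and is consistent with the moderate
bootstrap values the approach reports on real data.  Practically: treat
tied or weakly supported nodes as unresolved, and read the strict consensus
of tied optima rather than any single best tree.

## Numerical choices

* Rounding of step matrices is half-away-from-zero at 2 decimals (base R's
  `round()` ties to even, which would make exported matrices depend on
  binary representation quirks).
* Score ties use absolute tolerance 1e-9; all tied trees are retained.
* Stepwise addition starts from the first three taxa of the seeded shuffle;
  insertion is greedy on the partial-tree score.
* Degenerate inputs: zero-length trees become flagged uninformative
  characters; empty character sets score 0 with a warning; an empty gene
  list is an error in the pipeline but yields empty output from the filter.

## Problem sizes used in validation

The shipped tests and the acceptance script run entirely on simulated data
at desk scale, chosen to exercise every code path while keeping the whole
suite in the low minutes: oracle equivalence on 500 random 4–6-taxon
characters; normalization on 1000 random trees; species-tree recovery on
20 independent 7-taxon, 200-gene simulations scored exhaustively over all
945 topologies; null calibration of the association scan on 1000 planted
null categories over 2000 genes; bootstraps of 10–100 replicates on 20–100
genes.  The worked 4-taxon example — costs {3.33, 5.00, 8.33, 10.00},
lengths 16.66 on the generating topology versus 21.66 on the alternatives —
is computed live in the examples and pinned in the tests.

```{r worked}
tr <- parse_newick("((A:1,B:2):1,(C:1,D:1):2);", gene_id = "g1")
ch <- build_character(tr)
ch$cost
character_length(ape::read.tree(text = "((A,B),(C,D));"), ch)
character_length(ape::read.tree(text = "((A,C),(B,D));"), ch)
```

## Known limitations

* Exhaustive search is capped at nine taxa; the heuristic handles more but
  the package targets the small-taxon, many-gene regime.
* Per-gene adaptive weighting (gene stationarity, internode certainty) is
  out of scope; all genes are weighted equally by construction.
* The chi-square machinery refuses tables with zero expected cells rather
  than falling back to an exact test.
* The NEXUS reader parses only this package's own export dialect; it is a
  round-trip check, not a general NEXUS parser.
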