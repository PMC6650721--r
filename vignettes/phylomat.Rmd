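---
title: "Supermatrix construction and posterior diagnostics: models, defaults and design"
author: "phylomat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Supermatrix construction and posterior diagnostics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of the science behind each stage:
what is modelled, which knobs matter, what the synthetic data do and do not
emulate, and where a design was genuinely open and a choice had to be made.

## Scope and data model

`phylomat` covers the desk-side half of a phylogenomic study: turning gene
family trees and per-gene amino-acid alignments into partitioned, trimmed,
optionally recoded supermatrices, and auditing the tree samples an external
Bayesian sampler returns. It deliberately does **not** estimate gene trees,
cluster orthogroups, or run site-heterogeneous MCMC — those are external,
and the pipeline marks the boundary by writing the sampler's input format
(interleaved PHYLIP plus a command template) and consuming its
one-tree-per-line output format.

Trees are `ape::phylo` objects throughout. Analysis treats topologies as
unrooted; consensus trees are rooted for display only. Splits (bipartitions)
are stored canonically — the side *not* containing the lexicographically
first taxon of the universe, sorted — so equality and hashing are
order-independent, and every split carries its taxon universe: samples whose
trees lack some taxa (e.g. after rogue masking) are only pooled after
restriction to a common taxon set. Supermatrix partitions use 0-based
half-open ranges internally (single-site index vectors in R code are 1-based
column indices); Nexus charset output converts to the 1-based inclusive
convention.

## Gene-tree grooming

Three operations, applied in a fixed order (isoform masking, divergent-tip
removal, long-branch splitting), since each changes what the next sees:

* **Isoform masking.** Every maximal tip set that is monophyletic on the
  unrooted topology and single-species is collapsed to one representative.
  The keep rule prefers the longest ungapped sequence when sequences are
  supplied (the usual convention for transcriptome isoforms) and falls back
  to the smallest sequence id; the rule is a free choice — nothing in the
  underlying biology picks a winner among near-identical isoforms.
* **Divergent-tip removal** drops tips whose terminal branch exceeds
  `factor` (default 10) times the *median* terminal branch, in one pass. The
  median rather than the mean keeps the reference robust to the very
  outliers being removed; one pass rather than a fixed point keeps the
  operation predictable and order-stable.
* **Long-branch splitting** cuts internal branches above an absolute cutoff
  (default 1.5 substitutions/site) and keeps the resulting components of at
  least 4 tips as subfamilies. The cutoff is absolute because the deep
  paralogy it targets shows up as absolutely long stems, not as outliers
  relative to the family's own scale.

## Species-overlap orthology

A side of the unrooted family tree qualifies as an orthologue candidate if
no species occurs twice among its tips and it holds at least `minTaxa`
(default 3) species. Candidate sides are the non-trivial bipartition sides
plus the entire family; single tips and their complements are excluded — a
lone paralog hanging off a terminal edge must not certify everything else as
one orthologue. Maximal candidates can overlap; since concatenation needs at
most one sequence per species per gene, overlaps are resolved greedily by
descending species count with lexicographic tie-breaking on the sorted
sequence ids. Greedy disjointness is a pragmatic choice: the optimal
(weighted set-packing) resolution is NP-hard and the overlap cases are rare
and small.

## Gene selection and ranking

"Represented" means at least one occupied site, where occupied is any symbol
other than `?`: a gap (`-`) is an aligned, observed deletion while `?` is
absence of data, and occupancy statistics should separate the two. Selection
rules are conjunctions (minimum taxa, minimum combined counts over clade
sets, required taxa), so strengthening any component is monotone. Clade
minima use the *combined*-count reading of "at least three each of clade A +
clade B" by default; the per-clade reading is expressible as two entries —
the phrasing is genuinely ambiguous and both readings are kept available.

The informativeness ranking replaces quartet-geometry matrix reduction with
a documented, exactly testable proxy: `(taxon fraction) x (sites) x (1 -
gap/missing fraction)`. It preserves the pipeline role (rank and cut) while
being recomputable in one line.

## Site trimming

Per column the score is Shannon entropy of the residue frequencies,
normalized by `log(20)`, computed after two kinds of smoothing:

* **Similarity smoothing** (on by default): frequencies are multiplied by a
  kernel `(1 - w) I + w K`, `w = 0.3`, where `K` is the row-normalized
  non-negative part of BLOSUM62. A column mixing biochemically similar
  residues (one exchange group) then scores lower than one mixing dissimilar
  residues, which is the behaviour a saturation-targeting trimmer needs.
* **Window smoothing**: a centred moving average (default window 3),
  shrinking at the edges, because problematic columns cluster in regions.

Sites are kept when the smoothed score is at most `entropyCutoff` (default
0.5) **and** the gap/missing proportion is at most `gapCutoff` (default
0.2). A column with no informative symbol scores 1. Raising the entropy
cutoff always keeps a superset of sites. On a supermatrix the partition
table shrinks consistently and emptied genes are dropped.

Dayhoff-6 recoding maps AGPST→A, C→C, DENQ→D, FWY→F, HKR→H, ILMV→I, writing
each group as its alphabetically first member so recoded data stay inside
the amino-acid alphabet and every downstream writer works unchanged;
ambiguity codes (B, Z, J, X, U, O) become `?`. Recoding never changes
dimensions or gap placement, so a keep mask computed on the original
alphabet commutes with it.

## Posterior diagnostics

`maxdiff` is the maximum over all observed splits of the largest pairwise
absolute frequency difference between chains, with absent splits at
frequency 0 — one number per analysis, invariant to chain order, with the
conventional acceptance reading "below 0.2". Default burn-in is 20% of each
chain (the conventional choice; it is configurable because nothing in the
statistic fixes it).

Per-taxon **instability** is 1 minus the mean pooled frequency of the
taxon's *attachment split* (its smallest containing non-trivial split) over
the pooled sample: a taxon whose local neighbourhood never changes scores 0;
a taxon reattached at random scores near 1. In an unresolved sample with no
non-trivial splits a taxon is trivially stable (frequency 1 convention).

**Rogue flagging** greedily masks the taxon whose removal most reduces the
*support deficiency* `(n - 3) - sum of consensus split frequencies` — the
support mass missing relative to a fully resolved, fully supported topology
on the retained taxa — stopping when the best gain falls below
`gainThreshold` (default 0.5, i.e. half a fully supported position). Two
subtleties forced this exact formulation. First, masking a taxon removes one
resolvable split from the universe along with the taxon, so the raw count of
majority splits stays constant even when masking a maximally unstable taxon
fully resolves the remainder: a uniformly reattached taxon leaves every
other split a placement variant with expected frequency `(2b-1)/(2n-3) >
1/2` (sides of sizes `a <= b`), so no retained split ever drops out of the
majority in expectation. Second, the two placement variants of one split are
nested, hence mutually compatible, and can both clear 0.5, so a bare
compatible-split count can spuriously credit the consensus with having
"resolved" the wanderer. The support-mass deficiency is immune to both
effects and directly measures what masking is for: higher support
throughout.

The **masked consensus** prunes the masked taxa from every sampled tree,
then adds splits in descending pooled frequency while above the threshold
and compatible with those already accepted. With the default strict-majority
threshold, accepted splits are automatically compatible; thresholds below
0.5 abort on the first incompatibility rather than silently resolving it.
Annotations are pooled frequencies; branch lengths are not summarized (the
sampler's length treatment is not modelled here, and split frequencies are
the quantity the diagnostics reason about).

## The synthetic-data generators

The generators define the study conditions for every recovery test:

* **Species trees** are pure-birth (Yule) trees: waiting times are
  exponential with rate `k x rate` at `k` lineages, trees are ultrametric,
  and the expected height has the closed form `(1/rate) sum_{k=2..n} 1/k`
  used as an oracle. Multi-clade trees are built hierarchically (a Yule
  backbone over clades, a Yule subtree per clade) so named clades are
  monophyletic by construction.
* **Gene families** follow a birth-death copy process along the species
  tree (duplication and loss per copy per unit branch length); the expected
  family size `sum_i exp((dup - loss) depth_i)` is the oracle. With both
  rates zero the gene tree is congruent with the species tree, which anchors
  the orthology tests.
* **Alignments** evolve under an equal-exchangeability (F81-style) 20-state
  model with gamma rates — chosen because closed-form transition
  probabilities keep the simulation exact and fast, and because the tests
  target compositional signal, not exchangeability realism. Compositional
  bias is planted as a branch-local shift of the equilibrium frequencies
  (log-normal perturbation, default magnitude 1) with an extra substitution
  rate (default 20 per unit branch length) on biased sites inside the biased
  clade, in contiguous blocks (default 10 columns): biased and saturated
  regions cluster locally in real alignments — the same assumption behind
  window smoothing — and the rate boost is what makes the planted sites
  *saturated* as well as shifted on the shallow trees used at desk scale.
* **Tree-sample chains** emit the reference topology with probability
  `1 - scatterProb`, otherwise one random NNI; a planted rogue is detached
  and reattached to a uniformly chosen branch in every sample. This emulates
  a well-converged posterior plus an unplaceable taxon; it does not emulate
  autocorrelation, multimodality, or within-chain trends, so passing
  diagnostics here show correctness of the summaries, not robustness to
  every pathology of real MCMC.

What the generators do **not** emulate, and the tests therefore cannot
certify: CAT-style site-heterogeneous profiles, indels and alignment error,
codon structure, lineage-specific rate variation beyond the planted bias,
and real transcriptome occupancy patterns (occupancy is configurable, not
calibrated, because no quantitative occupancy distribution was available to
target).

## Numerical and calibration choices

* Default study conditions for end-to-end recovery: 16 taxa, 30 genes of
  600 sites, duplication and loss at 0.05, Yule rate 8 (tree height ~0.3-0.4
  substitutions/site — a shallow, conserved-ortholog regime). These sizes
  were fixed once so that the information content suffices for
  distance-based recovery: the residual failures are trees whose shortest
  internal edge is below ~0.002 substitutions/site, where no method can
  resolve the split from this much data. Diagnostics tests use 12-taxon
  references with 100-2,500 samples per chain.
* Trimming defaults (entropy 0.5, gap 0.2, window 3, similarity weight 0.3)
  were calibrated against the planted-bias generator's defaults to the
  stated recovery targets (at least 80% of planted sites removed, at most
  10% collateral).
* The neighbor-joining stand-in uses Poisson-corrected p-distances over
  sites occupied in both rows, `d = -(19/20) log(1 - 20p/19)`, with
  saturated pairs capped above the largest finite distance and negative
  estimated branch lengths clamped to zero.
* Newick output is canonical (children ordered by smallest contained tip
  label, fixed decimal precision), making artifacts diffable and
  de-duplication of sampled topologies a string comparison.
* All generators are bit-reproducible given a seed, and `runPipeline()`
  output depends only on (configuration, inputs, seed), verified by hashing.

## Known limitations

Grooming thresholds and the UPhO `minTaxa` are exposed configuration with
field-typical defaults, not values fitted to any dataset. The
chi-square-style composition statistic is descriptive — phylogenetic
correlation among taxa means it should be compared between matrices, not
against nominal chi-square quantiles. The rogue search is greedy and
one-taxon-at-a-time; a pair of taxa that are only jointly rogue would be
found one member at a time or not at all. Consensus trees report split
frequencies only.
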