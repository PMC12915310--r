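---
title: "Comparing phylogeny, biosynthetic potential, and metabolomes: models and design choices"
author: "panconcord"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing phylogeny, biosynthetic potential, and metabolomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panconcord)
```

# What the package models

A strain collection is observed through three channels: a phylogenetic tree,
the presence/absence of gene cluster families (GCFs) derived from predicted
biosynthetic gene clusters (BGCs), and metabolite feature tables from
fermentations under several media. `panconcord` quantifies which grouping
factor — phylogeny, isolation source, or culture medium — structures each
channel, using dendrogram concordance statistics with leaf-permutation
nulls, Mantel tests, PERMANOVA, and random-forest variance attribution.

Because raw strain collections are rarely shareable, the package treats its
synthetic-data generator as a first-class module: every analysis stage can
be exercised against data whose effect sizes are known exactly.

# The synthetic generator

## Phylogeny and groups

`simulate_tree()` draws a pure-birth (Yule) tree: exponential waiting times
between speciation events, birth rate 1, no extinction. This is the simplest
model producing realistic topology and branch-length variation; the marker-
protein likelihood trees used for real collections are consumed as Newick
input, never estimated here. Isolation sources are assigned uniformly at
random (four levels by default: soil, desert, water, host), and clades are
cut from the tree itself (average-linkage clustering of patristic distances,
four clades by default) so that "clade" is a genuinely phylogenetic factor.

## GCF content

Each GCF evolves independently down the tree as a two-state (present/absent)
continuous-time Markov chain with symmetric rate `gain_loss_rate` per unit
branch length and a fair-coin root state. Low rates produce strong
phylogenetic signal in the presence matrix; at high rates the leaf states
approach independent Bernoulli(1/2) draws (a property the tests check
against an iid simulation). An optional `source_fraction` of GCFs instead
track one isolation source, for experiments that need non-phylogenetic
structure in gene content.

Defaults: 40 GCFs at rate 0.3. Under the symmetric chain every strain
carries about half the families, i.e. roughly 20 BGCs per genome — the
scale reported for genus-level actinomycete collections. The emitted
antiSMASH-style BGC table contains one record per GCF present in a strain:
real cluster predictions enumerate everything they find, and subsampling
them would (and, in an earlier draft of the generator, did) destroy the
phylogenetic structure of any presence matrix rebuilt from the tables.

## Metabolomes

Log-abundance of feature *f* in the sample of strain *s* grown in medium
*m* is

    mu_f + sigma_medium * a[f,m] + sigma_phylo * b_f * z_s
         + sigma_source * c[f, src(s)] + sigma_noise * eps

with `a`, `b`, `c`, `eps` independent standard normal draws and `z_s` a
Brownian-motion trait on the tree (variance equal to the root-to-leaf path
length, via `ape::rTraitCont`). Abundances are exponentiated, so they are
nonnegative and right-skewed like peak areas. Channelling the phylogenetic
effect through a Brownian trait rather than through GCF content makes the
three variance knobs orthogonal by construction: recovery experiments are
not confounded.

The default effect sizes are `sigma_medium = 1.0`, `sigma_phylo = 0.3`,
`sigma_source = 0.0`, `sigma_noise = 0.5` (standard deviations on the log
scale): a medium-dominated metabolome with a modest phylogenetic component
and no source effect, which is the qualitative situation the package is
designed to detect. `mu_f ~ N(8, 1)` sets an arbitrary but realistic
peak-area scale. 95% of features are flagged as carrying MS2 spectra
(configurable), and pathway categories are sampled with weights mirroring an
annotated 650-feature molecular network (alkaloids-dominated, ~13% unknown).
One sample per strain × medium is generated by default; a replicate knob
exists because real designs vary and none is prescribed.

## Coordinate tables

Gene calls are 1-based inclusive, non-overlapping intervals on two contigs
per genome (one for very small genomes); 200 genes per genome by default —
deliberately scaled down from the ~6,000 of a real actinomycete genome,
since only the interval arithmetic matters. Each BGC spans a contiguous run
of 2–4 genes with a one-gene buffer between runs, so ground-truth
biosynthetic-gene labels are exactly "fully contained in a BGC interval".
Similarity-to-known-cluster scores mix point masses at 0 (~21%) and 100
(~2.5%) with a low-skewed continuous body, mimicking the novelty-heavy
profile of underexplored genera. Pan-genome cluster ids mix universal,
patchily shared, and genome-private clusters so partitions are non-trivial.

# Analysis-side models and conventions

## Pan-genome partitioning

A cluster is core iff present (≥ 1 copy) in *every* genome, singleton iff
present in exactly one. Presence, not copy count, drives the rule: a paralog
expansion should not eject a universal cluster from the core. All-zero rows
are dropped with a warning (merged exports commonly carry them); a strict
mode errors instead. Note one direction of monotonicity that follows from
the rule: removing a genome can only grow the core, never shrink it.

## Gene-to-BGC classification

Default mode is full containment (`bgc.start ≤ gene.start` and
`gene.stop ≤ bgc.stop`, same genome and contig, strand ignored);
`any-overlap` is available behind a flag. A gene matching several BGCs is
assigned to the smallest span, ties broken by lexicographically smallest
BGC id — overlapping cluster predictions are rare but must resolve
deterministically. Records with inverted coordinates are rejected with a
logged warning rather than an error, because they occur in real exports.

## Dissimilarities and trees

Jaccard (binary) and Bray-Curtis dissimilarities are computed via
`vegan::vegdist`; the package adds the double-zero convention (two empty
profiles get distance 0, with a warning) because both indices are undefined
there. UPGMA is the default linkage: it is the standard partner of
cophenetic analysis, yields ultrametric trees directly comparable to a
phylogram, and no linkage is ever prescribed in practice reports. Complete
and Ward linkages sit behind a flag. Merge heights are stored as half the
merge distance so that the cophenetic distance (2 × height of the lowest
common merge) reproduces the input distance for a two-leaf tree; toolchains
that report raw heights differ by exactly this factor of two. Ties in the
minimum inter-cluster distance are broken by the lexicographically smallest
member pair, making dendrograms reproducible.

Whether tree comparison should use strain-level metabolomes (mean over a
strain's samples) or sample-level ones is genuinely open; the package
aggregates to strain level when comparing against the strain-level tree
(`aggregate_by_strain()`) and keeps samples separate for PERMANOVA and
forests. Normalization defaults to total-ion-current scaling followed by
`log1p` — TIC is the least-assumption choice for untargeted tables and the
log stabilizes Bray-Curtis against single dominant features; `tic` and
`none` are exposed because the right choice is data-dependent.

## Merge levels and Baker's Gamma

The merge level k(i,j) is the largest number of clusters k, cutting the tree
into its k highest-level clusters, at which leaves i and j still co-occur.
For dendrograms the cut sequence follows merge heights from the root; for a
(possibly non-ultrametric) phylogram, internal nodes are cut in order of
increasing distance from the root, which reproduces the height-cut sequence
on ultrametric trees. Nodes at exactly equal depth break simultaneously —
this makes a star topology give k = 1 for every pair, and resolved
polytomies (which carry zero-length edges) behave like the polytomy they
came from. Basal polytomies are accepted as rooted stars; the Newick
representation cannot distinguish them from unrooted trees, and erroring
would reject legitimate star hierarchies.

Baker's Gamma is the Spearman correlation (midranks) of the two label-paired
merge-level vectors; a Pearson-on-levels dialect is exposed because
toolchains differ. The leaf-permutation null holds both topologies and all
heights fixed and permutes only the leaf labels of the second tree; since
relabeling merely permutes the pair vector, ranks are computed once and
permuted, which is exact and fast. One-sided (greater) p-values with the
plus-one correction are the default — concordance alternatives are positive —
and p can therefore never be exactly zero. Each statistic gets its own
permutation p; the package does not designate one of them as "the" null
model result.

## PERMANOVA and PCoA

PERMANOVA uses the classical distance-based sums of squares (formulas in the
README); permutations are unrestricted label shuffles by default, with a
`strata` argument for designs that need within-stratum permutation (e.g.
permuting medium within strain). The unrestricted default matches how the
test is usually reported. If SS_within is zero, F is +Inf and the p-value
still comes from the permutation distribution. PCoA reports all eigenvalues,
counts the negative ones, and drops their axes without Lingoes/Cailliez
correction: a correction would silently change coordinates, and the negative
part is worth seeing.

## Random-forest variance attribution

Each grouping criterion becomes the *response* of a regression forest whose
predictors are the profile columns, so OOB R² = 1 − MSE_oob/Var(y) measures
how well the data predict the grouping. Defaults: 5,000 trees in pipeline
use (tests and desk runs use 500, which is ample for R² stability at these
sizes), mtry = ⌈p/3⌉, minimum node size 5. The forest engine is
`randomForest`, seeded, so results are bit-reproducible.

Encoding group labels as numbers is the largest unstated analytic decision
in this kind of study. Two-level criteria are encoded 0/1. For unordered
multi-level criteria the package defaults to one-vs-rest (one forest per
level; R² and importances averaged): integer-coding the levels imposes an
arbitrary ordering, and in recovery experiments it diluted a real clade
signal to the point of being indistinguishable from the null source
criterion in a fifth of replicates. `integer_codes` remains available as an
explicit flag for comparability with toolchains that use it.

%IncMSE importance is reported as the unscaled per-tree mean increase in
OOB MSE normalized by the ensemble OOB MSE (×100). This is a
ratio-of-means rather than a mean of per-tree ratios — the engine does not
expose per-tree MSEs — and is 0 exactly for features never split on. The
SD-scaled variant used by some toolchains is available via
`permutation_importance(fit, scaled = TRUE)`.

# Numerical conventions

* Distance matrices must be symmetric to 1e-12 with zero diagonals; label
  pairing is always by name, never by matrix order, and label mismatches
  error with the symmetric difference.
* Permutation counts below 99 are rejected (p resolution too coarse);
  the pipeline default is 999.
* PCoA eigenvalues within `1e-8 × max|eigenvalue|` of zero are treated as
  zero.
* All stochastic stages derive their seeds deterministically from one global
  seed and a stage name, so stages can be rerun in isolation.

# What the tests do and do not show

The test suite checks the machinery against independent oracles (brute-force
double loops, `stats::hclust`/`cophenetic`, `cutree` cut-oracles, graph
shortest paths, `vegan::adonis2`/`mantel`, classical ANOVA on 1-D Euclidean
data), calibrates the permutation tests under true nulls (rejection rate
within three Monte-Carlo standard deviations of α over 500 replicates), and
runs parameter-recovery experiments at the default study conditions
(15 strains, 2 media, 300 features, 20 seeds): the medium PERMANOVA is
significant and the source one is not in ≥ 90% of replicates, forest R²
orders medium > clade > source, and the Mantel test couples GCF Jaccard to
patristic distances under slow gain/loss.

Passing these tests shows the chain recovers known structure from data that
satisfy the generator's assumptions: log-normal abundances, orthogonal
variance components, homogeneous per-branch gain/loss, complete and correct
metadata. Real LC-MS tables add missingness, batch effects, correlated
features, and adduct redundancy; real BGC tables add fragmented assemblies
and boundary errors. None of those are modelled, so a clean recovery here is
evidence about the statistics, not a validation of any particular biological
conclusion.

# Known limitations

* No sequence-level simulation (no FASTA/reads) and no mass spectra; the
  generator starts at the table level.
* GCF membership is consumed, never recomputed; orthology inference and
  ANI/dDDH computation are out of scope.
* The forest module is regression-only (no Gini importance, no boosting).
* PERMANOVA is one-way; no db-RDA, dispersion tests, or pairwise post-hocs.
* Dendrogram export assumes ultrametric heights; phylograms pass through
  unchanged but are never re-rooted.
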