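# panconcord

Integrative concordance analysis of phylogeny, biosynthetic gene cluster
(BGC) content, and untargeted metabolomes for bacterial strain collections.

## The problem

Natural-product discovery programs routinely assemble a set of related
isolates (e.g. actinomycetes of one genus), predict their BGCs, group them
into gene cluster families (GCFs), ferment the strains under several media,
and measure LC-MS/MS metabolite feature tables. The recurring scientific
question is: **what structures the observed chemistry — phylogeny, the
environment the strains were isolated from, or the culture medium?**
Answering it requires comparing three very different objects on the same
strain set:

* a phylogenetic tree (patristic distances),
* a GCF presence/absence profile (Jaccard dissimilarities), and
* a metabolite feature table (Bray-Curtis dissimilarities),

with honest null models for every comparison. `panconcord` implements that
comparison stack end to end, plus the pan-genome bookkeeping around it, and
ships a seeded synthetic-data generator with known effect sizes so the whole
chain is testable without any external data.

## The statistics at the core

For two hierarchies on the same leaves the package computes

* **cophenetic Pearson correlation** — Pearson *r* over the n(n−1)/2
  label-paired entries of the two cophenetic (or patristic) matrices;
* **Baker's Gamma** — Spearman rank correlation of per-pair *merge levels*
  k(i,j), the largest number of clusters k at which leaves i and j still
  share a cluster when the tree is cut into its k highest-level clusters;
* a **leaf-permutation null**: topology and heights fixed, labels of the
  second tree permuted, one-sided p = (1 + #{null ≥ observed}) / (n_perm + 1).

For two distance matrices it computes the **Mantel test** (permutation of
one matrix's rows/columns, reporting r and r²), and for grouped samples the
**PERMANOVA pseudo-F**

    SS_total = (1/n) Σ_{i<j} d²_ij
    SS_within = Σ_g (1/n_g) Σ_{i<j ∈ g} d²_ij
    F = (SS_between/(g−1)) / (SS_within/(n−g))

with permutation p-values, and **PCoA** (Gower double-centering, negative
eigenvalues reported and dropped). Variance attribution across grouping
criteria uses regression random forests (out-of-bag R² = 1 − MSE_oob/Var(y),
%IncMSE permutation importance).

Around that core: pan-genome partitioning (core = present in every genome,
singleton = exactly one, accessory = otherwise), coordinate joins labelling
genes as biosynthetic when fully contained in a BGC interval, BGC novelty
summaries from similarity-to-known-cluster scores, and the ANI < 95% /
dDDH < 70% putative-novel-species rule.

## Worked example

```r
library(panconcord)
report <- run_pipeline(list(seed = 11, n_perm = 999, n_trees = 500,
                            simulate = list(n_strains = 15)))
print(report)
```

```
Pipeline run report (seed 11 )
  stages: partition, bg_profile, novelty, category_composition, mantel, concordance, permanova, rf
  verdict (grouping criteria ranked by RF R2):
    1. medium   R2 = 0.981 [PERMANOVA significant]
    2. clade    R2 = 0.002
    3. source   R2 = -0.220
```

The simulated collection (15 strains, two fermentation media, a
medium-dominated metabolome and slowly evolving GCF content) is analysed the
same way a real bundle of input files would be. The concordance table shows
the designed structure being recovered:

```
> report$tables$concordance
               comparison cophenetic_pearson pearson_p bakers_gamma gamma_p n_perm
1 phylogeny_vs_metabolome              0.145     0.070        0.140   0.087    999
2        phylogeny_vs_gcf              0.818     0.001        0.887   0.001    999

> report$tables$permanova
  grouping pseudo_F r_squared     p df_between df_within
1   medium   36.875    0.5684 0.001          1        28
2    clade    0.785    0.0830 0.662          3        26
3   source    0.434    0.0477 0.969          3        26
```

GCF content tracks the phylogeny tightly (Baker's Gamma 0.887, p = 0.001
against the leaf-permutation null); the metabolome does not (p ≈ 0.07–0.09),
and only the culture-medium grouping is significant under PERMANOVA — the
random-forest verdict ranks medium ≫ clade > source. Real data enter through
an `inputs` block of file paths (Newick tree, gene-call and BGC TSVs,
MZmine-style quantification CSV with metadata sidecars) instead of the
`simulate` block; `validate_run_config()` schema-checks a bundle before
anything runs.

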