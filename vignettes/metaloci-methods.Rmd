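---
title: "Meta-locus discovery from local genetic correlations: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Meta-locus discovery from local genetic correlations: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metaloci)
```

# The scientific problem

Global genetic correlations summarize the shared genetic architecture of two
traits in a single number, but that number can hide strong, regionally
opposed signals: a cognitive phenotype may correlate negatively with
schizophrenia risk in one part of the genome and positively in another.
Local genetic correlation methods estimate, for each of ~2353 LD-independent
genomic segments, the genetic covariance and a correlation z-score between a
cognitive dimension -- cognitive task performance (CTP) or the non-cognitive
factor of educational attainment (NCF) -- and each of a panel of
psychopathological traits.

A *meta-locus* is a set of LD-independent segments, scattered across the
genome, that share a similar profile of these local correlation z-scores
across the trait panel. `metaloci` implements the discovery of such
meta-loci and their downstream characterization: which genes they harbor,
which biological gene sets those genes enrich, and whether the driver genes
are expressed prenatally or in adulthood.

# Stage 1: the global correlation matrix

The global cognitive x psychopathology genetic-correlation matrix is
analyzed two ways. `pca_with_loadings()` extracts principal components over
the psychopathology profiles and reports, for each cognitive trait, the
Pearson correlation between its correlation profile and each component
score vector -- the "loading" of that trait on the component.
`cluster_scan()` clusters the psychopathological traits on the Euclidean
distance between their profiles with four methods (k-means, k-medoids via
`cluster::pam`, Ward agglomeration, divisive clustering via
`cluster::diana`), growing k from 2 until any method isolates a singleton;
fit indices are min-max scaled across solutions and summed, and
`select_solution()` breaks near-ties by bootstrap Jaccard stability.

# Stage 2: meta-locus discovery

The core procedure takes the segments x traits z-score matrix (MHC segments
removed; window chr6:25-35 Mb on hg19, configurable) through five steps.

**Clustering tendency.** `hopkins()` computes the Hopkins statistic
H = sum(u) / (sum(u) + sum(w)), comparing nearest-neighbour distances of
uniform reference points (u) and sampled real points (w) under the
convention where spatially random data gives H near 0.5 and clustered data
approaches 1. `shuffle_null()` permutes all matrix cells -- preserving the
value multiset while destroying row structure -- and summarizes H over 20
shuffles, giving a data-specific random reference level.

**Embedding ensemble.** `umap_ensemble()` fits `n_models` seeded 2-D
neighbourhood-preserving embeddings and stacks their coordinates into a
segments x (2 * n_models) feature matrix. The embedder is of the
uniform-manifold family: a fuzzy k-nearest-neighbour graph with smooth,
locally adaptive bandwidths (solved so each point's effective neighbourhood
weight is log2(k)), symmetrized by fuzzy union, then laid out in 2-D by
stochastic gradient descent with negative sampling under the standard
attraction curve 1/(1 + a d^(2b)) fitted from `min_dist`. It is written
in-package (C++ core) so that the determinism-under-seed contract holds
exactly: the graph stage is deterministic, and the layout RNG is seeded
per model, with the default seed vector being consecutive integers from
one master seed. Defaults follow the analysis design: `n_neighbors = 5`,
`min_dist = 1/sqrt(n)` (0.0206 at n = 2353), a local-connectivity fraction
of 0.7 mapping the assumption that about 70% of manifolds show local
connections, and 200 optimization epochs, which at these problem sizes is
past the point where cluster recovery stops improving.

**Embedding diagnostics.** `embedding_diagnostics()` reports replicate
stability (mean pairwise |Pearson r| across seeded models after testing
both dimension pairings and both sign flips, since stochastic replicates
are only defined up to axis permutation and reflection), plus
trustworthiness T and continuity C -- the standard rank-based penalties for
invented and lost k-neighbourhoods -- and their product, "retention", as a
single structure-preservation score.

**Density scan.** `knn_elbow_eps()` sorts the distances to each point's
5th nearest neighbour and finds the elbow automatically as the point of
maximum perpendicular distance from the chord joining the curve's
endpoints (the curve and index are returned for audit, since automated
elbow detection replaces a visual judgement). `dbscan_scan()` fits the
density clustering at the base radius and at `eps0 + eps0 * j` for
j = 1..5; at the largest radius compact data typically collapses into one
cluster. Each model records its silhouette distribution over non-noise
points (median, mean, 75th percentile, maximum); models with negative
median silhouette are rejected as misclassifying.
`select_dbscan_model()` scores the survivors by the sum of five min-max
scaled components -- the three silhouette summaries, the classified-point
count and the negated noise count -- balancing cluster quality against
information retention, and picks the maximum.

**Hierarchical refinement.** The density solution captures local cluster
patterns; to recover global ones, `hierarchical_refine()` augments the
ensemble features with a one-hot encoding of density-cluster membership
(noise rows all-zero; block weight 1 by default) and cuts a Ward tree at
each candidate k in {5, 10, 15, 25, 30}. Candidates are compared on a
five-index fit panel; each index ranks the candidates, and the k with the
most indices in its top 3 wins (ties by the larger summed scaled score).
Density-scan noise points stay unclassified (label -1).

## The fit-index panel

Both the Stage-1 scan and the refinement share one panel: average
silhouette width, Calinski-Harabasz, the Dunn index, Pearson gamma (the
correlation between dissimilarities and the different-cluster indicator),
and a negated distance-based Davies-Bouldin index (scatter = mean
within-cluster dissimilarity, separation = mean between-cluster
dissimilarity). All are computed from the distance matrix and oriented
larger-is-better. The fifth slot deliberately uses Davies-Bouldin rather
than the within/between sum-of-squares ratio: that ratio is strictly
monotone in k, so under a top-3 rank rule it always credits the largest
candidates and biases refinement toward over-splitting, whereas every
index in this panel peaks at genuine structure.

## Calibration on the Iris fixture

`load_iris_fixture()` serves the canonical 150 x 4, three-species table
(from the copy shipped with R) as the ground-truth calibration dataset for
the ensemble -> density-scan -> refinement pipeline. The pipeline recovers
all three species as clusters, with extra species-pure sub-clusters
permitted. Perfect per-cluster species purity, however, is not attainable
for this method family on raw Iris: five flowers have a majority of
cross-species 5-nearest-neighbours in the original feature space, so any
neighbourhood-faithful embedding places them inside the other species'
cloud, and density clustering inherits the error. The test suite asserts
the strict purity criterion and documents its failure rather than relaxing
it; typical runs misplace only a few flowers out of 150.

# Stage 3: genes, gene sets, trajectories

**Gene prioritization.** `prioritize_genes()` filters a multi-method
evidence table by per-method percentile rank (rank at or better than
`ceiling(N * 0.5)` by default), with transcriptome methods averaged by rank
across their annotation sources. Genes whose heterogeneity (HEIDI-style)
p-value is significant lose their transcriptome support -- significant
heterogeneity indicates the expression-mediation signal is likely driven by
linkage, so it is removed rather than sign-flipped (the source procedure's
"inversion" is not given an algebra; removal is the conservative reading).
The final list is the union of per-method survivors with credible
fine-mapped genes. `assign_genes_to_metaloci()` places each gene by the
segment containing its midpoint, and `inverse_rank_score()` maps a
unidirectional ranking onto [0, 1) as `1 - rank/N`, with the worst gene at
exactly 0 -- computed within the per-meta-locus universe, because the
downstream enrichment runs per meta-locus and the meta-locus gene lists
partition the genome.

**Enrichment.** `gsea_preranked()` implements the preranked running-sum
statistic: walking the score-ordered gene list, in-set genes add
`score / sum(in-set scores)` and misses subtract `1/(N - N_hits)`; the
enrichment score is the signed maximum deviation, and the in-set genes at
or before the peak are the leading-edge *driver genes*. The null permutes
the gene-score assignment (equivalently: redraws the set's positions)
1000 times; NES divides by the mean same-sign null ES and FDR follows the
pooled null-NES estimate. Set sizes are bounded to [15, 500] after
intersection with the universe. `hypergeometric_ora()` provides the
secondary over-representation evidence (upper-tail `phyper`,
Benjamini-Hochberg FDR, minimum overlap 3, sizes 5-2000), and
`consensus_sets()` applies the consensus rule: primary significance in the
running-sum analysis plus support from at least one over-representation
result (a reduced-redundancy collection may use a relaxed 0.1 threshold).

**Trajectories.** `recode_weeks()` maps post-natal ages onto a continuous
developmental-week scale (`years * 52 + 37`; 8 to 2117 weeks).
`aggregate_driver_expression()` averages driver-gene expression per sample
and meta-locus, and `fit_lmm()` fits random-intercept mixed models via
`lme4`: per meta-locus `expression ~ weeks + sex + (1 | donor)`, and for
the CTP-vs-NCF comparison `expression ~ weeks * trait + sex + (1 | donor)`
against the weeks-only null by a likelihood-ratio test on ML fits (trait
main effect + interaction enter together, so df = 2). Wald tests use the
normal approximation, which is adequate at developmental-atlas sample
sizes. `classify_trajectory()` maps a significantly negative weeks
coefficient to "prenatal", significantly positive to "adulthood", and
non-significance to "lifetime". The direction follows the trajectory
results themselves (prenatally expressed gene sets decline with age on
this scale); brain region is not modelled as a fixed effect, matching the
source model, though the generator produces region-structured samples.

# The synthetic-data generator

Because the real inputs are GWAS-derived supplementary downloads, every
input is emulated with planted ground truth:

- `simulate_segment_map()` tiles the 22 hg19 autosomes (embedded constant
  lengths; chromosome X excluded, as the LD segmentation covers autosomes)
  into n non-overlapping segments allocated proportionally to chromosome
  length.
- `simulate_local_rg()` plants `k_true` latent clusters with per-trait mean
  z profiles (drawn from Normal(0, profile_sd^2), default spread 2) plus
  Normal(0, noise_sd) within-cluster noise (default 0.5); unassigned noise
  segments draw z ~ Normal(0, 1) and carry label -1. Heritabilities are
  gamma draws with mean 1e-4 per segment -- the order observed for highly
  polygenic cognitive phenotypes, so that summed heritability over ~2330
  segments lands near 0.23 -- and covariance is derived as
  `tanh(z / 10) * sqrt(h2_a h2_b)`, which keeps the implied correlation
  sign-consistent with z (the z-to-covariance link is a modelling choice;
  the source reports both quantities without specifying their joint
  generative form).
- `simulate_gene_evidence()` drives all evidence columns from one latent
  per-gene effect, boosted in designated driver clusters, and plants
  enriched gene sets by oversampling high-effect genes.
- `simulate_expression()` generates donor x region x gene records with
  donor random intercepts and linear trajectories of +-0.003 expression
  units/week (matching the scale of reported interaction effects), ages
  uniform on [8, 2117] weeks.

What the generator does *not* emulate: SNP-level LD, realistic eQTL
structure, heteroskedastic z-score noise across segment sizes (a
per-segment SE multiplier would be the natural extension), non-linear
expression trajectories, and correlated gene sets. Passing tests therefore
demonstrate that the machinery recovers planted structure of the stated
form -- not that real local-rg data contains such structure.

# Numerical and design choices

- **Seeds.** Every stochastic operation takes an explicit integer seed or
  derives one from a master seed via a fixed affine map; reruns of a
  pipeline config are byte-identical.
- **Ties.** Ranking ties break by stable input order (then gene id);
  k-means uses 10 seeded starts; minmax scaling maps constant index
  columns to 0.5 (uninformative).
- **Degenerate inputs.** All-identical rows make the Hopkins statistic
  undefined (error); an all-equal k-NN distance curve short-circuits with
  eps = that distance; single-cluster density models carry NA silhouettes
  and enter selection at the indifferent value 0; a singleton at the
  smallest scanned k keeps those solutions with a warning so the scan is
  never empty.
- **Refinement input.** The hierarchical step runs on the stacked ensemble
  features (not one arbitrary replicate) -- the ensemble is the stabilized
  representation -- with density membership as a weighted one-hot block.
- **Aggregated global rg.** The signed ratio
  `sum(cov) / sqrt(sum(h2_a) * sum(h2_b))` is used; a square root over the
  whole ratio would destroy the sign that the concordance comparison with
  LDSC-style estimates requires.

# Problem sizes used by the tests and acceptance script

Desk-scale validation uses the study's own shapes where that is what is
being checked -- 2353 segments, MHC exclusion to ~2330, 17 traits, k_true
in {5, 10, 15} with 20 seeds for recovery (median adjusted Rand index >=
0.9 and chosen k = k_true); calibration checks use 1000 x 2 uniform
matrices for the Hopkins band, 2000 null gene sets for the permutation
type-I error, 500 null simulations for the likelihood-ratio test, and 100
simulations for slope recovery. Unit tests run the same operations at
smaller sizes with exhaustive or closed-form oracles (brute-force
silhouettes, an exhaustive running-sum walk, hypergeometric tail sums, an
independent standard implementation for the enrichment score).

# Known limitations

- The embedder is a faithful but compact implementation of its family;
  it does not expose every knob of mature libraries (metrics other than
  Euclidean, supervised embedding, transform of new points).
- Meta-locus counts on real data are not deterministic reproductions:
  the embedding ensemble is stochastic by design, and only its seeded
  reproducibility -- not a specific cluster count -- is guaranteed.
- The LRT for the trait comparison tests fixed effects only; trait-level
  random slopes are not modelled.
- Druggability annotation is a plain symbol join against a user-supplied
  tier table; no identifier harmonization is attempted.
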