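---
title: "Models and methods behind netstab"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind netstab}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netstab)
```

netstab asks, of a sample-by-taxon count table, three linked questions: how do
the communities differ (diversity, ordination, permutation tests), what
assembled them (phylogenetic and taxonomic null models), and how stable is the
web of co-occurrences they form (network construction, robustness,
vulnerability, cohesion, keystone analysis, environmental drivers). This
vignette records the models, the defaults and why they were chosen, the
numerical edge cases, and what the synthetic-data generator does and does not
emulate.

## The data model

Counts are compositional: each sample is closed to its library size, so only
relative information is observable. All diversity and correlation stages work
on within-sample relative abundances. Analyses are organized per *group*
(host-by-condition cells of a design, each typically around 21 samples), and a
separate co-occurrence network is built per group, because pooling groups
mixes between-group contrasts into within-group correlation structure.

## Diversity and ordination

Alpha diversity reports Shannon entropy (natural log), the Gini–Simpson index
`1 − Σ p²`, Pielou evenness `H / ln S` (undefined when a sample holds one
taxon; reported as missing), and bias-corrected Chao1
`S + F1(F1 − 1) / (2(F2 + 1))`, which stays defined when no doubletons exist.
Between-sample dissimilarity is Bray–Curtis on relative abundances; it is a
semimetric, so the triangle inequality is deliberately not asserted anywhere.
Principal coordinates use Gower double-centering; negative eigenvalues —
expected for semimetric input — are retained in the report but excluded from
the proportion-explained denominator, matching common practice; a Cailliez
correction is available by flag. PERMANOVA (Anderson's pseudo-F, via vegan)
and ANOSIM provide group tests with permutation p-values of resolution
`1/(n_perm + 1)`; 999 permutations by default. Group comparisons of alpha
diversity use Welch's t-test by default (a pooled-variance flag exists):
unequal variances cost little when variances happen to be equal and protect
the test when they are not.

## Community assembly null models

βMNTD (between-community mean nearest taxon distance) is the
abundance-weighted mean patristic distance from each taxon to its closest
relative in the paired community, averaged over both directions. βNTI
z-scores the observed βMNTD against a null in which taxon labels are shuffled
across the tree tips — richness and abundances preserved — with 999 shuffles
by default; this is the classic taxa-label null. Pairs whose null spread
collapses to zero (e.g., two communities sharing every taxon, where every
shuffle still yields zero nearest-taxon distance) are flagged as degenerate
and assigned βNTI 0 rather than dropped, so the pair set stays complete.

The taxonomic complement is Raup–Crick on Bray–Curtis: each null community
redraws the sample's observed richness with selection probability
proportional to occupancy, then fills to the observed total abundance in
proportion to pool-wide relative abundance. The observed dissimilarity's rank
within the null distribution is rescaled to [−1, 1], ties counted half.

Sample pairs are then partitioned into five processes with the standard
thresholds: βNTI > 2 heterogeneous selection, βNTI < −2 homogeneous
selection; otherwise RC > 0.95 dispersal limitation, RC < −0.95 homogenizing
dispersal, and the remainder drift. Signed selection thresholds (rather than
a one-sided reading) are required for the five categories to be mutually
exclusive and exhaustive, which the partition asserts on every input: the
five fractions always sum to 1.

## Co-occurrence networks

Edges are Spearman correlations across the samples of one group, kept only
when `|ρ| > 0.6` **and** `p < 0.01`, both strict. Mid-ranks handle ties.
p-values use the exact permutation distribution for tie-free samples of size
≤ 9 (at n = 4 the smallest two-sided p is 1/12, so no edge can clear 0.01 —
the construction refuses nothing, the threshold does the work) and the
t approximation otherwise. No multiple-testing correction is applied by
default, because the thresholded-|ρ| construction is the convention this
analysis follows; Benjamini–Hochberg is one flag away, and with it the edge
set can only shrink. Constant taxa have undefined correlations; their pairs
are skipped with a warning. Isolated taxa remain nodes.

Modules come from Louvain modularity maximization on the unweighted edge
presence graph (signed weights would need a different quality function), run
under a fixed seed for determinism. Node roles use the within-module degree
z-score Zi (0 when a module's degree spread is 0) and the among-module
connectivity `Pi = 1 − Σ (k_is/k_i)²` (0 for isolated nodes), classified at
the conventional thresholds Zi 2.5 and Pi 0.62; everything that is not
peripheral — connectors, module hubs, network hubs — is a potential keystone.
Path length and diameter are computed over the largest connected component in
unweighted hops, the convention of the common network GUIs; local clustering
counts nodes of degree < 2 as 0.

## Stability metrics

**Global efficiency** is the mean inverse hop distance over all node pairs
(disconnected pairs contribute 0); **vulnerability** is the largest relative
efficiency loss any single node deletion can cause, defined as 0 for an
edgeless graph.

**Robustness** simulates random loss of 50% of taxa followed by a secondary
extinction cascade. Each survivor's abundance-weighted mean interaction
strength over surviving neighbors, `wMIS_i = Σ b_j ρ_ij / Σ b_j`, is
recomputed each round, and every node at or below the extinction threshold
(default 0) is removed simultaneously; the cascade runs to a fixed point and
the replicate reports the fraction of original taxa remaining. Simultaneous
removal plus a fixed threshold makes each replicate deterministic given the
removal set. Survivors left with no neighbors have wMIS 0 and therefore die
under the default rule; this is intentional — it lets the remaining fraction
drop below `1 − removal_fraction` and carries the information that separates
fragile from redundant networks. Both the threshold and the rule are exposed
as arguments. 100 replicates by default; replicate vectors are returned so
group comparisons (Welch or paired t) can be run on them.

**Cohesion** scores each taxon's connectedness as the mean of its positive
(and, separately, negative) pairwise correlations after subtracting a
taxa-shuffle null expectation (200 shuffles by default; the null correction
removes structural correlation that closure alone induces), then sums
abundance × connectedness within each sample. The negative:positive ratio
`|neg|/pos` is the per-sample stability proxy — more negative relative to
positive cohesion means more of the web is antagonistic, which buffers
cooperative cascades. It is undefined (missing) when positive cohesion is 0.
Pearson correlation is the default here, matching the cohesion literature,
while the network stage uses Spearman, matching the network literature.

**Keystone removal** deletes all non-peripheral nodes at once and reports the
vulnerability change with its sign. Removing a star's center, for example,
takes vulnerability from 1 to 0 — the metric is conditional on the surviving
graph, so interpretation should always pair ΔV with the node count removed.

## Drivers of stability

Keystone importance regresses a per-sample stability response on keystone
relative abundances with a random forest and reports out-of-bag %IncMSE;
significance comes from refitting under response permutation,
`p = (1 + #{perm ≥ obs}) / (1 + n_perm)` with 100 permutations by default.
The response defaults to per-sample N:P cohesion because robustness and
vulnerability are per-network quantities — there is one value per group, not
per sample; any per-sample metric can be substituted.

Environmental forward selection adds greedily on adjusted-R² gain and accepts
a variable only when the gain is positive and its permutation p ≤ 0.05, with
ties broken by column order and machine-collinear candidates skipped with a
warning. The path model is a set of ordinary least squares equations on
z-scored variables — standardized path weights, so a single-predictor
coefficient equals the sample correlation — with direct/indirect/total
effects obtained by exhaustive enumeration of directed paths (the acyclicity
check names any cycle it finds). This deliberately reproduces the quantities
a piecewise structural equation analysis reports (standardized coefficients,
per-equation R², effect decomposition) without the d-separation test, which
is out of scope here.

## The synthetic-data generator

`simulate_counts()` emulates a processed amplicon table at the design scale
of a four-group, 21-samples-per-group study: latent multivariate normal
scores with block covariance (within-module correlation 0.8, between 0.1 by
default), exponentiated onto a log-normal abundance spectrum (σ = 1) and
closed by multinomial sampling at depth 10,000. Half the taxa belong to
modules (`module_coverage = 0.5`); the rest are uncorrelated background. The
background matters twice over: real communities carry many unstructured taxa,
and a fully modular community largely cancels its own correlation signal
under closure because the shared module factors dominate every sample's
total. A fraction (0.3) of module members carry negated loadings, producing
negative within-module correlations while keeping the covariance
positive-semidefinite; any residual non-PSD-ness from user-chosen correlation
values is repaired by clipping eigenvalues at 1e-10 and re-normalizing the
diagonal. With these defaults, about 94% of planted within-module pairs among
filter-surviving taxa pass the ρ > 0.6, p < 0.01 screen at 84 pooled samples
— the generator is strong enough to exercise every downstream stage.

`simulate_assembly()` plants assembly regimes for null-model validation:
Brownian traits on a Yule tree (unit birth rate, height rescaled to 1) with
Gaussian environmental filtering around two contrasting optima (selection),
colonization from contiguous windows of the pool (dispersal limitation), or
uniform draws (drift). `simulate_env()` draws variables from a user-declared
linear DAG so that path-model recovery can be checked against known
standardized coefficients.

What the generator does **not** emulate: sequencing error and chimeras, taxon
relative-abundance overdispersion beyond the log-normal, phylogenetic signal
in the abundance spectrum, temporal autocorrelation across sampling months,
and true host effects — groups share one covariance and differ only by
sampling noise. Passing tests therefore demonstrate that the machinery
measures what it claims on data whose structure is known, not that any
particular biological system behaves this way.

## Numerical choices and problem sizes

Stage seeds are derived deterministically from a master seed and the stage
name, so no stage consumes global randomness and reruns are byte-identical.
Default null/permutation counts are 999; the test suite and worked examples
run the same code at reduced sizes (99–199 nulls, 10–30 robustness
replicates, groups of 12–21 samples and 60–300 taxa) chosen as the smallest
sizes at which every qualitative property the suite asserts is stable across
seeds. Degenerate inputs are contracts, not surprises: empty samples,
constant taxa, zero-variance modules, edgeless graphs, sd-zero null
distributions and zero positive cohesion each have a documented value or a
typed error, and the tests exercise all of them.

## Known limitations

Spearman-threshold networks inherit compositional bias; the generator
documents that this bias is part of what the analysis sees, and
compositionality-aware inference (SparCC-style) is intentionally out of
scope. The robustness cascade's extinction rule is one of several in the
literature; both its threshold and its update scheme are arguments, and
conclusions should be checked for sensitivity to them. Vulnerability is a
worst-case single-node quantity and says nothing about multi-node attack
tolerance. The path model assumes linearity and no latent confounding; it
quantifies association structure consistent with a DAG, not causal effects.
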