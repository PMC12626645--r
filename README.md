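# netstab

**netstab** measures the stability of microbial communities from
sample-by-taxon count tables — the kind produced by 16S/amplicon pipelines —
and asks what maintains it. It was built for host-associated microbiome
studies that compare groups of hosts across environmental conditions (for
example, gut microbiota of two gastropod species inside and outside
cyanobacterial blooms), but every function takes an ordinary count matrix or
data frame, so any grouped community data fits.

The package covers, end to end:

- **Diversity and ordination** — Shannon, Gini–Simpson, Pielou, bias-corrected
  Chao1; Bray–Curtis dissimilarity; PCoA; PERMANOVA and ANOSIM with
  permutation p-values.
- **Community assembly** — βMNTD/βNTI phylogenetic null models (tip-shuffle
  null, Rcpp-accelerated) and Raup–Crick on Bray–Curtis, partitioned into the
  five classical processes: pairs with βNTI > 2 reflect heterogeneous
  selection, βNTI < −2 homogeneous selection, and the remainder split by
  RC > 0.95 (dispersal limitation), RC < −0.95 (homogenizing dispersal), or
  drift.
- **Co-occurrence networks** — signed Spearman networks with the strict
  |ρ| > 0.6, p < 0.01 screen, topology metrics, Louvain modules, and Zi–Pi
  node roles (module hubs Zi ≥ 2.5 & Pi < 0.62, network hubs Zi ≥ 2.5 &
  Pi ≥ 0.62, connectors Pi ≥ 0.62; everything non-peripheral is a potential
  keystone). GraphML export is Gephi-ready.
- **Stability** — robustness as the proportion of taxa surviving random
  removal of 50% of nodes plus the secondary-extinction cascade on
  abundance-weighted mean interaction strength (wMIS); vulnerability as the
  worst single-node loss of global efficiency
  `E = mean(1/d(i,j))`; per-sample positive/negative cohesion
  (`Σ abundance × connectedness`) and the negative:positive ratio;
  keystone-removal tests.
- **Drivers** — random-forest %IncMSE keystone importance with permutation
  p-values, forward selection of environmental variables, and a standardized
  linear path model with direct/indirect/total effect decomposition.
- **Synthetic data** — a generator with recorded ground truth (planted
  correlation modules, assembly regimes, driver DAGs) so the whole pipeline
  is testable without sequencing data.

Results come back as tibbles (or small S3 objects with `tidy()`, `glance()`
and `autoplot()` methods), so everything composes with dplyr and ggplot2.

## Worked example

```r
library(netstab)

# a synthetic study with known structure: 2 groups x 12 samples, 60 taxa
study <- simulate_study(synth_config(n_samples_per_group = 12, n_groups = 2,
                                     n_taxa = 60, sequencing_depth = 4000,
                                     seed = 42))

counts_g1 <- study$counts[study$metadata$group == "G1", ]
filtered <- filter_taxa(counts_g1)      # > 0.1% mean abundance, > 1/3 prevalence
net <- build_network(filtered)
net
#> Signed co-occurrence network: 59 nodes, 91 edges ( 51 positive / 40 negative )
#> thresholds: |rho| > 0.6 , p < 0.01

modules <- detect_modules(net, seed = 1)
roles <- zipi(net, modules)
table(roles$role)
#>  peripheral   connector  module_hub network_hub
#>          58           1           0           0

robustness(net, seed = 1)
#> Robustness: 0.146 +/- 0.052 (100 replicates, 50% removal, 59 nodes)

vulnerability(net)
#> [1] 0.3099237

coh <- cohesion(filtered, connectedness(filtered, seed = 1))
head(coh, 3)
#>   sample_id cohesion_pos cohesion_neg np_ratio
#> 1 s_G1_01          0.257       -0.222    0.862
#> 2 s_G1_02          0.262       -0.229    0.874
#> 3 s_G1_03          0.293       -0.233    0.797
```

Reading the numbers: after deleting half the 59 nodes at random, the cascade
of secondary extinctions (taxa whose surviving interactions sum to nothing
positive) leaves on average 14.6% of the original taxa — a fragile network,
consistent with its worst single node accounting for 31% of global
efficiency. The N:P cohesion around 0.8–0.9 says negative (competitive)
interactions nearly balance positive ones in every sample.

The whole per-group pipeline — filter, assembly partition, network, roles,
stability, keystone importance, drivers — runs in one call with deterministic
stage seeding:

```r
cfg <- netstab_config(seed = 42)                 # defaults: 999 nulls, 100 reps
res <- run_pipeline(study$counts, study$metadata, study$tree, study$env,
                    config = cfg, out_dir = "results/run1",
                    dag = list(np_cohesion ~ WT + MCs))
res$summary    # one row per group: nodes, edges, modularity, drift fraction,
               # robustness, vulnerability, N:P cohesion, keystones, ...
```

Re-running with the same config writes byte-identical outputs.

## Learn more

The methods vignette (`vignettes/network-stability-methods.Rmd`) documents
the models and their assumptions, every tunable default and why it was
chosen, what the synthetic generator does and does not emulate, and the
numerical edge-case conventions.
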