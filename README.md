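# metabnet

Inter-subject **metabolic covariance networks** from regional FDG-PET
values, with graph-theoretical characterization and permutation-based group
comparison.

In FDG-PET, regional glucose metabolism is summarized as one value per
brain region per subject. Regions whose metabolism covaries across the
subjects of a group are taken to be functionally coupled, so each *group*
yields one network: nodes are the 90 AAL regions, edges the strongest
across-subject Pearson correlations. `metabnet` implements the full
analysis used in this literature, for researchers comparing patient and
control cohorts (e.g. diabetes, dementia) from ROI-level PET tables:

- **Atlas**: the AAL-90 parcellation (45 regions per hemisphere, cerebellum
  excluded) with a functional classification
  (association/paralimbic/subcortical/primary) used to summarize hub
  composition — `load_region_table()`, `classify_composition()`.
- **Preprocessing**: per-subject global-mean normalization and per-region
  OLS residualization against age, sex and fasting glucose —
  `global_normalize()`, `residualize()`.
- **Networks**: Pearson matrix across subjects, binarized by connection
  density (fraction of the N(N−1)/2 possible edges, ranked by |r|) over the
  10–40% sweep — `pearson_matrix()`, `density_threshold()`,
  `density_sweep()`.
- **Graph metrics**: clustering coefficient `C = mean(2eᵢ/kᵢ(kᵢ−1))`,
  characteristic path length `L = mean(L_ij)`, betweenness centrality
  `B(i) = Σ n_jk(i)/n_jk` (Brandes), normalized betweenness
  `bᵢ = B(i)/mean(B)`, and small-world indices against degree-preserving
  random references: `γ = C/C_random`, `λ = L/L_random`, `σ = γ/λ` (σ > 1:
  small-world). Hubs are regions with `bᵢ > 1.5` — `small_world()`,
  `identify_hubs()`, `shared_hubs()`.
- **Inference**: group-relabeling permutation tests that rebuild both
  networks from scratch in every permutation, for global metrics across the
  density sweep and for nodal betweenness at a fixed density, plus the
  betweenness-distribution correlation check —
  `global_permutation_test()`, `nodal_permutation_test()`,
  `centrality_distribution_correlation()`.
- **Synthetic cohorts** with a known ground-truth covariance topology
  (ring-rewired latent graph, distance-decay correlations, covariate
  confounds, positive globally-scaled values) for validation and power
  exploration — `cohort_spec()`, `generate_cohort()`,
  `generate_null_pair()`.
- **Orchestration**: `run_pipeline()` runs everything and writes TSV/JSON
  artifacts; `exec/metabnet` exposes the stages as shell subcommands
  (`simulate`, `preprocess`, `network`, `metrics`, `permtest`, `run`).

## Worked example

```r
library(metabnet)

# a synthetic diabetic-vs-control style cohort: 73 + 91 subjects, 90 regions
coh <- generate_cohort(cohort_spec(seed = 7))

# per group: normalize, residualize covariates, correlate, binarize at 10%
corr_a <- pearson_matrix(preprocess_panel(coh$panel_a))
corr_b <- pearson_matrix(preprocess_panel(coh$panel_b))
net_a  <- density_threshold(corr_a, 0.10)
net_a
#> Binary network: 90 nodes, 400 edges (density 0.0999), |r| cutoff 0.3058

set.seed(7)
small_world(net_a, n_random = 100)
#> Small-world indices (density 0.100, 100 random references)
#>   C = 0.3201  (random 0.0969)  gamma  = 3.303
#>   L = 2.4697  (random 2.2756)  lambda = 1.085
#>   sigma = gamma/lambda = 3.044
```

The network is small-world: clustering 3.3× its degree-matched random
references (γ = 3.30) at near-random path length (λ = 1.09), σ = 3.04 > 1.

```r
rt <- load_region_table()
hubs_a <- identify_hubs(nodal_centrality(net_a, rt), rt)
head(hubs_a, 5)
#>   index abbreviation hemisphere  func_class        b
#> 1    53          IOG          L association 3.868626
#> 2    77          THA          L subcortical 2.703627
#> 3    50          SOG          R association 2.600930
#> 4    12     IFGoperc          R association 2.424792
#> 5    86          MTG          R association 2.375120
```

16 regions exceed b > 1.5 in group A (each row: canonical node index,
abbreviation, hemisphere, functional class, normalized betweenness).
Comparing the groups' centrality profiles:

```r
net_b <- density_threshold(corr_b, 0.10)
centrality_distribution_correlation(nodal_centrality(net_a)$b,
                                    nodal_centrality(net_b)$b)
#> $r
#> [1] -0.04044023
#> $p
#> [1] 0.7053626
```

The two groups' betweenness profiles are uncorrelated — expected here,
since this cohort's group B received a 10% topological perturbation and
sample betweenness at this scale is noisy. The permutation test makes that
precise (no per-density clustering difference is declared):

```r
g <- global_permutation_test(coh$panel_a, coh$panel_b,
                             metrics = "C", n_perm = 100, seed = 8)
g
#> Global permutation test (100 relabelings, alpha 0.05, tail 'auto')
#>   C      significant at: none
```

`g$table` holds, per metric and density, the observed difference, the
95th-percentile critical values of the permutation null, one-sided and
two-sided empirical p-values, and FDR-adjusted flags.

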