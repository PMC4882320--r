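---
title: "Metabolic covariance networks: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Metabolic covariance networks: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The model

FDG-PET measures regional glucose metabolism, one number per region per
subject once an anatomical parcellation is applied. Across subjects of a
group, regions whose metabolism rises and falls together are taken to be
functionally coupled: the *metabolic covariance network* of a group is the
graph on the 90 AAL regions whose edges are the strongest inter-regional
Pearson correlations of regional metabolism across that group's subjects.
Unlike fMRI connectivity there is one network per *group*, not per subject
— the correlation is computed over subjects, so group comparison needs the
relabeling machinery described below rather than subject-level statistics.

The pipeline is:

1. **Global-mean normalization** (`global_normalize()`): each subject's 90
   regional values are divided by their whole-brain mean. PET uptake is
   positive and globally scaled per subject (dose, weight, scanner gain);
   dividing by the global mean removes that factor exactly. A known side
   effect, discussed under *Limitations*, is that removing the common mode
   depresses all inter-regional correlations and can introduce
   anticorrelation.
2. **Covariate residualization** (`residualize()`): per region, OLS
   residuals of the normalized value on an intercept plus age (years), sex
   (0/1) and fasting blood glucose (mmol/L). Residualization is per group
   by default — each group's network is built from its own subjects, and
   per-group fitting cannot leak group-mean differences into both networks.
   A rank-deficient design (e.g. a constant sex column) is an error naming
   the offending column; missing covariates are an error, not imputed.
3. **Correlation and binarization** (`pearson_matrix()`,
   `density_threshold()`): the 90 x 90 Pearson matrix is thresholded by
   *connection density* — the fraction of the N(N−1)/2 possible edges kept
   — rather than by a raw correlation cutoff, so the two group networks
   always have the same edge count and metric differences are topological,
   not density-driven. Edges are ranked by |r|; anticorrelations count
   (`positive_only = TRUE` is available as a sensitivity mode). Because no
   single density is privileged, analyses sweep 10–40% in 1% steps
   (31 networks); 10% is the customary lower anchor, the smallest density
   at which the network typically spans all 90 regions.
4. **Graph metrics** (`nodal_clustering()`, `characteristic_path_length()`,
   `betweenness_centrality()`, `small_world()`): clustering coefficient
   C_i = 2e_i / (k_i(k_i−1)) averaged over all nodes; characteristic path
   length as the mean BFS shortest-path length over all pairs; betweenness
   B(i) as the sum over pairs {j,k} of the fraction of shortest j–k paths
   through i (endpoints excluded, unordered pairs — the standard Freeman
   convention), computed by Brandes' algorithm. Normalized betweenness
   b_i = B(i)/mean(B) has mean 1 by construction; a node with b_i > 1.5 is
   a *hub*.
5. **Small-world normalization**: C and L are divided by their means over
   degree-preserving random references (double-edge-swap randomization,
   `random_reference()`), giving gamma = C/C_random, lambda = L/L_random
   and sigma = gamma/lambda. sigma > 1 (large gamma, lambda near 1) is the
   small-world signature.
6. **Inference** (`global_permutation_test()`, `nodal_permutation_test()`):
   subjects are repeatedly reassigned to two pseudo-groups of the original
   sizes and the *entire* construction — residualization on the
   pseudo-group, correlation, thresholding, metric — is recomputed, giving
   the permutation null of the between-group difference. One relabeling
   sequence is reused across densities and metrics, so per-density results
   are comparable. Empirical p-values use the (b+1)/(n_perm+1) convention
   and can never be exactly zero.

# Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| density sweep | 0.10–0.40 step 0.01 | fraction of possible edges kept |
| nodal density | 0.10 | fixed density for hub/betweenness comparison |
| hub threshold | 1.5 | b_i above which a region is a hub (strict >) |
| n_random | 100 | random references for observed networks |
| n_random_refs (permutations) | 10 | references inside the permutation loop |
| n_perm | 1000 | relabelings (>= 20 enforced) |
| alpha | 0.05 | level; critical values at the 95th percentile |
| n_swaps_per_edge | 10 | attempted double-edge swaps per edge |

Random references inside the permutation loop default to 10 rather than
100: the references' Monte-Carlo noise enters both the observed and the
null differences and is absorbed by the percentile, while 100 references
per network inside 1000 permutations would dominate runtime. The number is
recorded in every result object.

# Choice of tail

The conventional report is a one-tailed decision at the 95th percentile of
the permutation distribution. Choosing the tail *after* looking at the sign
of the observed difference doubles the effective size (about 0.10 at
alpha = 0.05). `global_permutation_test()` therefore always reports both
one-sided p-values with their critical values, but its primary `significant`
flag defaults to `tail = "auto"`: |observed| compared with the null of
|differences|, a direction-agnostic test whose size is the nominal alpha
(verified empirically in the test suite: the rejection rate over 200
exchangeable null cohorts falls in the binomial 95% band around 0.05).
Fixed-direction one-sided flags (`tail = "greater"`/`"less"`) are also
size-correct and available when the direction is specified a priori. The
nodal test reports the two one-sided decisions separately
(`significant_decrease` / `significant_increase`), mirroring the way
reduced and increased centrality are reported in this literature.
Uncorrected flags are primary; Benjamini–Hochberg adjusted p-values across
densities (global) or regions (nodal) are reported alongside.

# The synthetic cohort generator

The package's study conditions are carried by `cohort_spec()`: two groups
of 73 and 91 subjects over 90 regions, ages about 57 ± 10 and 56 ± 8
years, mostly male (54/73 and 66/91), fasting glucose 8.4 ± 0.9 vs
5.1 ± 0.4 mmol/L — a diabetic-vs-control design. The generative model:

- A **latent graph** on the 90 regions: ring lattice of even degree 8 with
  each lattice edge rewired with probability 0.1 (Watts–Strogatz), kept
  connected, exact density 8/89. This is the regular/random interpolation
  that motivates the small-world indices; degree 8 puts the latent density
  (~9%) at the lower anchor of the analysis sweep.
- An implied **correlation matrix**: r_ij = 0.6 × 0.5^(d_ij − 1) with d_ij
  the graph distance (adjacent regions 0.6, geometric decay per hop),
  repaired to positive definiteness by eigenvalue clipping at 1e−6 and
  renormalization to unit diagonal; the repair's largest entry change is
  reported as an attribute.
- **Subject data**: regional log-signals are multivariate normal with that
  correlation, scaled by signal_sd = 0.15 log-units, plus independent noise
  (noise_sd = 0.3, relative — attenuating correlations by 1/(1+0.3²)),
  plus linear covariate effects (defaults −0.002/year age, 0.02 male,
  −0.01 per mmol/L glucose, all in log-units), exponentiated and multiplied
  by a lognormal (sd 0.2) per-subject global factor. The result is
  positive, globally scaled, mildly lognormal "metabolism-like" data whose
  nuisance structure is exactly what normalization and residualization are
  supposed to remove.
- **Group difference**: group B's latent graph is either identical
  (`group_b_perturbation = 0`, the exchangeable null used by
  `generate_null_pair()`), rewired by degree-preserving double-edge swaps
  on a stated fraction of edges (differences are then purely topological,
  at matched density and degree sequence — the default, fraction 0.1), or
  degraded at a chosen node (`perturb_target`): a fraction of that node's
  edges are moved elsewhere in the graph, planting a focal hub loss. The
  paper-style analyses report no effect sizes for network differences, so
  the perturbation magnitudes are calibration choices of this package, not
  empirical claims.

What the generator does *not* emulate: image-domain effects (no voxels,
no spatial smoothing, no partial-volume structure), scanner or site
effects, non-linear covariate dependence, heavy-tailed or skewed regional
distributions beyond the mild lognormal, and any realistic anatomical
ordering of the latent graph (latent neighbours are not spatial
neighbours). Passing tests on synthetic cohorts therefore validate the
*algorithms* — recovery of a known topology, calibration of the tests —
not the biological claims one might make from real PET data.

## A property worth knowing

Because the planted latent graph keeps every region within a few hops of
every other, the implied correlations have a substantial common positive
mode. Global-mean normalization removes the common mode, which depresses
every sample correlation by roughly the mean planted covariance (and can
flip weak ones negative) while preserving their ranking — the well-known
anticorrelation side effect of global normalization in PET. The test suite
therefore checks generator consistency on the latent (log, pre-
normalization) scale, where the sample correlation converges to the
planted matrix, and checks the pipeline's recovery of the planted *edge
set* (Jaccard ≥ 0.9 at n = 500) after normalization, where ranking is what
matters.

# Numerical choices and degenerate inputs

- **Ties at the density cutoff** are broken by larger |r|, then smaller
  row, then smaller column index: bit-reproducible, and immaterial on real
  data where ties have measure zero. Exactly round(density × N(N−1)/2)
  edges are kept.
- **C_i for degree < 2** is 0 and included in the mean, keeping C defined
  at sparse densities.
- **Disconnected networks**: `characteristic_path_length()` errors by
  default, naming the component sizes; a connected-pairs mode averages
  finite distances only and flags the result. Disconnected *random
  references* in `small_world()` use the connected-pairs mode and are
  counted rather than discarded — discarding would bias the reference
  toward connected, shorter-path graphs at sparse densities. Inside
  permutation loops the connected-pairs mode is used throughout, since
  pseudo-group networks occasionally disconnect.
- **All-zero betweenness** (e.g. complete graphs) makes b_i undefined;
  `normalized_betweenness()` returns NA with an `undefined` attribute
  rather than dividing by zero.
- **PD repair** of the distance-decay matrix: eigenvalue floor 1e−6, then
  cov2cor; distance-decay matrices are not guaranteed positive definite.
- **Determinism**: every stochastic entry point takes a seed and restores
  the caller's RNG state; identical config + seed reproduces pipeline
  outputs byte for byte.

# Problem sizes used by the test suite

Tests exercise reduced but fixed scales chosen to probe each property:
exhaustive oracle comparison on all ~990 connected labelled graphs with up
to 5 nodes plus sampled 6–8 and 10–12-node graphs; type-I error on 200
exchangeable null cohorts of 30 regions and 30 subjects per group with 200
relabelings (clustering coefficient at 20% density); small-world
calibration and planted-hub recovery at the full 90-region, 73/91-subject
design; generator consistency at n = 1500. The full suite runs in a few
minutes on one core.

# Known limitations

- The hub-composition summary depends on a functional classification of
  all 90 regions; only 35 region-hemisphere entries have published classes,
  and the remainder are completed by mirroring and by the Mesulam-style
  scheme (marked `mirrored`/`inferred` in the packaged table). Composition
  fractions for non-hub-heavy analyses should be read with that in mind.
- Group networks are built per group; with one network per group there is
  no subject-level variance estimate, and all inference is by relabeling.
- Weighted networks, partial correlations and sparse inverse covariance
  are out of scope; binarization at matched density is the supported mode.
- At realistic cohort sizes the sample betweenness of a single region is a
  noisy estimate of its latent centrality: the planted-hub recovery test
  needs the generator's strong-signal regime (edge_corr 0.85, decay 0.3,
  low noise) to flag a planted degradation at n = 73/91 — a statement
  about power, not about correctness of the test (whose size is verified
  separately).
- Global-mean normalization introduces the common-mode depression
  described above; no surrogate for it (e.g. regression against the global
  signal) is provided.
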