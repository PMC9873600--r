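# cbparcel

Connectivity-based parcellation of a subcortical seed structure — such as
the amygdala — from probabilistic-tractography streamline counts, in R.

## What it does

Diffusion tractography gives every voxel of a seed region a
*connectivity fingerprint*: the number of streamline samples terminating
in each of a set of target regions (here the standard seven-target design:
NAc, brainstem, hippocampus, DLPFC, insula, OFC, rACC). cbparcel turns a
cohort of such count maps into a population parcellation of the seed:

- **Connectivity matrix** `M` (seed voxel × target counts) and its
  **cross-correlation matrix** `CCM = cor(M rows)` per subject;
- **k-means** (Lloyd + k-means++, best of restarts, k = 3 by default) on
  the CCM rows, so voxels cluster by the similarity of their connectivity
  profiles;
- cross-subject **label harmonization** (exact minimum-cost assignment of
  cluster fingerprints to a cohort-median reference) and a **consensus
  map**: per cluster, each voxel's value is the number of subjects with
  that label there, thresholded at 50% of the cohort;
- **connection probabilities** per voxel, `p_t = n_t / Σ_t n_t` restricted
  to voxels whose total exceeds a sample threshold (1250 of 5000 by
  default), averaged over cluster voxels and subjects, with a one-way
  ANOVA + Bonferroni post-hoc comparing the k clusters per target;
- **group tract-map algebra** for cluster-seeded visitation maps:
  normalize to the map maximum → threshold at 0.95 → binarize → sum
  across subjects → subject-count threshold.

Everything runs against a built-in **synthetic tractography phantom**:
an ellipsoidal seed (~550 voxels, 1.25 mm) split into three contiguous
medial-to-lateral slabs, multinomial per-voxel counts of 5000 samples
from planted cluster profiles, logistic-normal profile noise and spatial
jitter emulating registration error. The planted ground truth makes every
stage testable, with recovery measured by the adjusted Rand index.

## A worked example

```r
library(cbparcel)

cfg <- pipeline_config(phantom = phantom_config(rng_seed = 1))
res <- run_pipeline(cfg, out_dir = "run1")
res$summary
#> # A tibble: 7 × 2
#>   statistic           value
#>   <chr>               <dbl>
#> 1 n_subjects            30
#> 2 n_seed_voxels        552
#> 3 consensus_ari          1
#> 4 pattern_fraction       0
#> 5 volume_mm3_cluster1  414.
#> 6 volume_mm3_cluster2  375
#> 7 volume_mm3_cluster3  289.
```

At the default noise and jitter the 30-subject consensus recovers the
planted three-slab parcellation exactly (`consensus_ari = 1`), even
though individual subjects' parcellations are noisy — the per-subject
mediolateral pattern flag (strict centroid ordering *and* 6-connected
contiguity per cluster) passes in 0% of these noisy subjects, rising to
100% on a noiseless phantom. Cluster volumes are the final consensus
masks times the voxel volume.

Per-cluster connection probabilities and the hippocampus ANOVA:

```r
fit <- res$anova$fit[[which(res$anova$target == "HC")]]
fit
#> <cluster_anova> HC (left): F(2, 87) = 2682, p = 6.8e-79
#>   significant pairs (Bonferroni): 1-2, 1-3, 2-3
tidy(fit)      # pairwise mean differences, raw and Bonferroni p
glance(fit)    # F, df, p in one row
autoplot(res$profile_table)   # cluster × target bars ± SE
autoplot(res$consensus)       # consensus labels, mid-axial slice
```

The basal (middle) cluster's hippocampal probability is the largest —
the phantom plants ~54% of its samples there — and all three cluster
pairs separate after Bonferroni correction.

A thin command-line driver is included:

```sh
Rscript inst/cli/cbparcel.R simulate --config cfg.yaml --out cohort/ --seed 17
Rscript inst/cli/cbparcel.R run --out run1/ --seed 17
```

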