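---
title: "Connectivity-based parcellation from tractography count maps: methods and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Connectivity-based parcellation from tractography count maps: methods and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cbparcel)
```

## The problem

Probabilistic tractography assigns to every voxel of a seed structure a
*connectivity fingerprint*: the number of streamline samples that reach
each of a set of target regions. When the seed is a heterogeneous nuclear
complex such as the amygdala, voxels with similar fingerprints can be
grouped into subregions that are not visible in conventional anatomical
images. cbparcel implements that workflow end to end for the common
seven-target design (nucleus accumbens, brainstem, hippocampus, DLPFC,
insula, OFC, rostral ACC):

1. per-subject **connectivity matrix**: seed voxel × target streamline
   counts, the region-level view of a probtrackx "matrix 2" output;
2. per-subject **cross-correlation matrix** (CCM): Pearson correlation of
   every pair of voxel fingerprints — the clustering feature space;
3. **k-means parcellation** of the CCM rows with k = 3, reflecting the
   gross centromedial / basal / lateral organisation of the amygdala;
4. cross-subject **label harmonization** and a **consensus map**: per
   cluster, the number of subjects carrying that label at each voxel,
   thresholded at 50% of the cohort;
5. **connection probabilities** per cluster (a proj_thresh emulation) and
   a one-way ANOVA with Bonferroni post-hocs comparing clusters per
   target;
6. **group tract-map algebra** (normalize → threshold at 0.95 → binarize
   → sum across subjects → subject-count threshold) for cluster-seeded
   visitation maps.

Because the real inputs are hundreds of tractography runs, the package
ships a synthetic **tractography phantom** whose planted ground truth
makes every stage testable on a laptop, with no imaging data.

## The phantom: what it emulates and what it does not

`phantom_config()` describes a cohort. The seed is an ellipsoid of ~550
voxels at 1.25 mm isotropic resolution (the dMRI resolution of modern
connectome protocols), placed in the left hemisphere and split into three
spatially contiguous slabs along the medial-to-lateral axis — the
arrangement the k = 3 amygdala parcellation is expected to recover. Each
slab owns a probability profile over the 7 targets (`default_cluster_profiles()`);
the basal cluster is dominated by hippocampal connectivity, mirroring the
strongest connection seen in real amygdala data.

Per seed voxel, the per-target counts are one multinomial draw of
`samples_per_voxel = 5000` streamline samples — the standard probtrackx
sampling depth — from the voxel's cluster profile. Inter-subject
variability has two knobs:

* **`profile_noise`** (default 0.2): the sd of a logistic-normal
  perturbation applied per subject and voxel to the log of the cluster
  profile before renormalisation. A logistic-normal was preferred over a
  Dirichlet because a single sd knob moves continuously from noiseless to
  heavily perturbed while preserving the simplex.
* **`jitter_sd`** (default 0.5 mm): spatial misalignment standing in for
  residual registration error after nonlinear normalisation. It is
  realised as a per-subject rigid translation of sd `jitter_sd` *plus* a
  per-voxel positional scatter of sd `jitter_sd / 2`. The scatter term
  matters: a purely rigid shift leaves the ordering of cluster centroids
  and their 6-connectivity invariant, so it could never degrade the
  per-subject pattern statistics that registration error visibly degrades
  in practice; the local component emulates the non-rigid part of the
  error and both blurs consensus boundaries and speckles individual label
  fields.

The defaults were calibrated once, as the package's reference study
condition: at noise 0.2 each subject's parcellation is visibly imperfect
(subject-level adjusted Rand index against the planted truth around
0.85), while the 30-subject consensus still recovers the truth with
ARI ≥ 0.9 across seeds. All randomness flows from one root seed;
per-subject streams are derived by stable hashing of (seed, subject
index), so cohorts are reproducible under subject-parallel generation.

The phantom does **not** simulate streamlines, diffusion signal, crossing
fibres, distance-dependent sampling bias, or realistic anatomy; passing
its tests shows that the *pipeline* recovers planted structure under
controlled noise, not that tractography itself is accurate on real
brains.

## Numerical choices

**Scan order and coordinates.** Seed voxels are enumerated x-fastest with
0-based indices; world coordinates are RAS millimetres via the volume's
affine. "Medial → lateral" means increasing |x| within a hemisphere.

**CCM.** Fingerprints are correlated on raw counts (no log transform; a
row-normalisation flag exists and defaults off). Voxels with all-zero or
constant fingerprints have no defined correlation; they are excluded from
the CCM, reported, and left unlabeled downstream rather than imputed.
The matrix is symmetrised against floating-point asymmetry and its
diagonal pinned to 1.

**k-means.** Lloyd's algorithm (via `stats::kmeans`) on the rows of the
CCM, squared-Euclidean distance, k-means++ initialisation, best of 20
restarts by inertia; restarts that collapse to an empty cluster are
re-seeded and counted. On every tested instance small enough to
enumerate (≤ 10 voxels), the returned inertia equals the exact optimum
over all partitions into 3 nonempty groups. Clustering raw fingerprints
instead of CCM rows is available through the `features` argument but is
not the default.

**proj_thresh.** A voxel's per-target probability is count / total with
total strictly greater than the threshold (default 1250, a quarter of the
5000 samples); a tie with the threshold is sub-threshold, and
sub-threshold voxels are zero everywhere rather than missing. The
per-voxel total is used as the denominator, so each suprathreshold
voxel's probabilities sum to exactly 1.

**Harmonization.** k-means labels are arbitrary per subject. Cluster
mean fingerprints (row-normalised to proportions) are matched to a
cohort-median reference by exact minimum-cost assignment — enumerated
over the k! permutations, which *is* the Hungarian optimum at k = 3 —
with ties broken lowest-label-first and logged. The reference frame is
built from a label-free provisional ordering (clusters ranked by distance
from the midline), so harmonizing twice equals harmonizing once. A purely
geometric `"anatomical-x"` reference is available as a fallback for
degenerate fingerprints.

**Consensus.** A voxel enters cluster c when at least
`ceiling(threshold_fraction × n_subjects)` subjects carry label c there
(≥, with the default 50%); overlaps resolve to the highest count, ties to
the lowest cluster index (logged). Both operation orders — threshold the
counts first and then resolve overlaps, or assign each voxel to its
highest-count cluster first and then threshold — are implemented; under
count-argmax resolution they provably coincide (the argmax cluster passes
the threshold whenever any cluster does), which the test suite asserts,
so the choice of default (`"threshold-then-resolve"`) is cosmetic.
Consensus is computed on the common grid *without* undoing the simulated
misalignment, letting jitter degrade agreement exactly as registration
error would in a real MNI-space analysis.

**ANOVA.** Observations are subject-level cluster means (voxels within a
cluster are not independent). The omnibus test is the standard one-way
fixed-effects ANOVA; post-hocs are pairwise two-sided pooled-sd t tests
with Bonferroni factor equal to the number of cluster pairs (3 for
k = 3) within each target × hemisphere. Zero within-group variance gives
F = 0 with p = 1 when the means agree and F = ∞ with p = 0 when they do
not, instead of NaN. Published analyses of this design sometimes report
much larger error degrees of freedom (pooling across targets or voxels);
the family and observational unit used here are deliberate, documented
choices, and the family size is what the Bonferroni factor reflects.

**Tract maps.** "Normalize" means division by the map's maximum, so the
0.95 threshold reads "95% of the map's peak"; waytotal-style
normalisation would need tractography internals that are out of scope.
Thresholds compare with ≥. The final group-level subject-count threshold
is a required, explicit parameter: in published work this step is guided
by anatomical judgement, which is not reproducible algorithmically, so
only the parameterised mechanism is provided (the pipeline defaults it to
the consensus count for convenience).

## Validation design

The test suite validates each stage against an independent oracle or a
planted truth:

* CCM vs a hand-coded pairwise Pearson formula (1e-12); k-means inertia
  vs exhaustive enumeration of all 3-group partitions on 8–10-voxel
  problems; assignment cost vs brute-force permutation search; ANOVA
  F/df/p vs the closed-form sum-of-squares decomposition (1e-10).
* Parameter recovery: at the documented defaults (30 subjects), the
  consensus-vs-truth ARI must reach 0.9, and 1.0 in the noiseless limit.
* The mediolateral pattern flag (centroid |x| order + per-cluster
  6-connectivity) holds in 100% of noiseless subjects and erodes
  monotonically with jitter.
* Type-I calibration: 1000 null cohorts (identical cluster profiles,
  tiny grid, 9 subjects) must give uncorrected p < 0.05 in 5% ± 1.5% of
  tests. The null ANOVA uses the planted cluster masks as the grouping:
  re-clustering pure noise and then testing the groups it found would
  select on the noise itself and inflate the rate by construction — the
  property under test is the calibration of the inference given fixed
  cluster definitions.
* Determinism: fixed seeds reproduce cohorts, parcellations and
  consensus maps bit-identically.

Problem sizes in the tests (tiny 8×7×6 grids for unit tests, the ~550
voxel default phantom for recovery, 20-subject cohorts for the pattern
series) are the package's reference configurations; they keep the whole
suite at a few minutes on one core while leaving every statistical check
adequately powered.

## A worked run

```{r, eval = FALSE}
cfg <- pipeline_config(phantom = phantom_config(rng_seed = 1))
res <- run_pipeline(cfg, out_dir = "run1")
res$summary
autoplot(res$profile_table)      # per-cluster connection probabilities
autoplot(res$consensus)          # consensus labels, mid-axial slice
glance(res$anova$fit[[3]])       # hippocampus ANOVA
```

## Known limitations

* Target-region granularity: fingerprints are counts to whole target
  regions (7 columns), not to every target voxel; a voxel-level-column
  connectivity matrix is out of scope.
* The phantom's noise is spatially independent across voxels; real
  registration error and tractography noise are spatially correlated, so
  consensus accuracy on real data will be lower at equal nominal noise.
* Jitter is translation + local scatter; rotations and scanner-specific
  distortions are not modelled.
* k is fixed by design (default 3); model selection for k (silhouette,
  gap statistics) is intentionally absent.
* The hemisphere of a cluster is derived from the sign of its centroid's
  world x; seeds straddling the midline should be analysed per
  hemisphere.
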