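Package: cbparcel
Title: Connectivity-Based Parcellation of Seed Regions from Tractography
    Count Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Parcellates a subcortical seed structure (such as the amygdala)
    from probabilistic-tractography streamline counts to a set of target
    regions. Builds per-subject seed-voxel connectivity matrices and their
    cross-correlation matrices (CCM), clusters seed voxels with k-means,
    harmonizes cluster labels across subjects, and derives thresholded
    cross-subject consensus cluster maps. Quantifies per-cluster connection
    probabilities (proj_thresh-style proportion maps) and tests cluster
    differences per target with one-way ANOVA and Bonferroni post-hoc
    comparisons, and implements the group tract-map algebra
    (normalize, threshold, binarize, sum). Ships a synthetic tractography
    phantom generator with planted, spatially contiguous clusters so the
    whole pipeline can be exercised and validated against known ground
    truth without any imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    mclust,
    purrr,
    RNifti,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
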