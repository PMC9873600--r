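# Small phantom configurations shared across test files.

tiny_config <- function(..., n_subjects = 3L, rng_seed = 42L) {
  phantom_config(grid_shape = c(8L, 7L, 6L), n_subjects = n_subjects,
                 samples_per_voxel = 5000L, rng_seed = rng_seed, ...)
}

# A noiseless, perfectly registered mini cohort (cheap, deterministic).
clean_cohort <- function(n_subjects = 3L, ...) {
  generate_cohort(tiny_config(profile_noise = 0, jitter_sd = 0,
                              n_subjects = n_subjects, ...))
}

# Build connectivity matrices / CCMs / parcellations for a cohort.
parcellate_cohort <- function(cohort, k = 3L, restarts = 10L, seed = 1L) {
  cms <- lapply(cohort$subjects, function(s) {
    build_connectivity_matrix(s$count_volumes, s$seed_mask,
                              subject_id = s$subject_id)
  })
  ccms <- lapply(cms, build_ccm)
  parcs <- lapply(seq_along(ccms), function(i) {
    kmeans_parcellate(ccms[[i]], k = k, seed = seed + i, restarts = restarts)
  })
  list(cms = cms, ccms = ccms, parcs = parcs)
}

# Volumes with a shared affine for hand-built fixtures.
toy_volumes <- function(counts, grid = c(2L, 2L, 2L), voxel = 1) {
  # counts: named list of vectors of length prod(grid)
  aff <- diag(c(voxel, voxel, voxel, 1))
  lapply(counts, function(v) as_volume(array(v, dim = grid), aff))
}
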