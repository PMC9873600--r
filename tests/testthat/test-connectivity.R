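test_that("the connectivity matrix is assembled row-per-voxel in scan order", {
  grid <- c(2L, 1L, 1L)
  aff <- diag(4)
  vols <- list(t1 = as_volume(array(c(3000, 1000), dim = grid), aff),
               t2 = as_volume(array(c(2000, 4000), dim = grid), aff))
  seed <- as_volume(array(TRUE, dim = grid), aff)
  cm <- build_connectivity_matrix(vols, seed)
  expect_equal(unname(cm$counts), rbind(c(3000, 2000), c(1000, 4000)))
  expect_equal(cm$target_names, c("t1", "t2"))
  expect_equal(cm$voxels, cbind(0:1, 0L, 0L), ignore_attr = TRUE)
})

test_that("degenerate connectivity inputs raise clear errors", {
  grid <- c(2L, 2L, 2L)
  aff <- diag(4)
  vols <- list(a = as_volume(array(1, dim = grid), aff),
               b = as_volume(array(1, dim = c(2L, 2L, 3L)), diag(4)))
  seed <- as_volume(array(TRUE, dim = grid), aff)
  expect_error(build_connectivity_matrix(vols, seed), "grid shape.*'b'")
  vols$b <- as_volume(array(1, dim = grid), diag(c(2, 2, 2, 1)))
  expect_error(build_connectivity_matrix(vols, seed), "affine.*'b'")
  vols$b <- as_volume(array(1, dim = grid), aff)
  expect_error(
    build_connectivity_matrix(vols, as_volume(array(FALSE, grid), aff)),
    "seed mask is empty"
  )
})

test_that("CCM reproduces an independent pairwise Pearson computation", {
  withr::with_seed(17, {
    counts <- matrix(rpois(24, 100), nrow = 6, ncol = 4)
  })
  vols <- toy_volumes(asplit(counts, 2L), grid = c(6L, 1L, 1L))
  names(vols) <- paste0("t", 1:4)
  seed <- as_volume(array(TRUE, c(6L, 1L, 1L)), diag(4))
  cc <- build_ccm(build_connectivity_matrix(vols, seed))
  expect_lt(max(abs(cc$ccm - oracle_pearson_matrix(counts))), 1e-12)
  # structural invariants
  expect_lt(max(abs(cc$ccm - t(cc$ccm))), 1e-10)
  expect_equal(unname(diag(cc$ccm)), rep(1, 6))
  expect_true(all(cc$ccm >= -1 - 1e-12 & cc$ccm <= 1 + 1e-12))
})

test_that("perfectly correlated and anticorrelated fingerprints hit +-1", {
  counts <- rbind(c(1, 2, 3), c(2, 4, 6), c(3, 2, 1))
  vols <- toy_volumes(asplit(counts, 2L), grid = c(3L, 1L, 1L))
  names(vols) <- paste0("t", 1:3)
  seed <- as_volume(array(TRUE, c(3L, 1L, 1L)), diag(4))
  cc <- build_ccm(build_connectivity_matrix(vols, seed))
  expect_equal(cc$ccm[1, 2], 1)
  expect_equal(cc$ccm[1, 3], -1)
})

test_that("zero and constant fingerprints are excluded with reasons", {
  counts <- rbind(c(5, 1, 9), c(0, 0, 0), c(4, 4, 4), c(1, 8, 2))
  vols <- toy_volumes(asplit(counts, 2L), grid = c(4L, 1L, 1L))
  names(vols) <- paste0("t", 1:3)
  seed <- as_volume(array(TRUE, c(4L, 1L, 1L)), diag(4))
  cm <- build_connectivity_matrix(vols, seed)
  expect_message(cc <- build_ccm(cm), "excluded 2")
  expect_equal(cc$used, c(1L, 4L))
  expect_equal(cc$excluded$reason,
               c("all-zero fingerprint", "constant fingerprint"))
  # fewer than 2 usable rows is an error
  vols2 <- toy_volumes(asplit(counts[2:3, ], 2L), grid = c(2L, 1L, 1L))
  names(vols2) <- paste0("t", 1:3)
  seed2 <- as_volume(array(TRUE, c(2L, 1L, 1L)), diag(4))
  expect_error(suppressMessages(
    build_ccm(build_connectivity_matrix(vols2, seed2))), "at least 2")
})

test_that("the CCM is invariant to target column order", {
  coh <- clean_cohort(n_subjects = 1L)
  s <- coh$subjects[[1]]
  cc1 <- build_ccm(build_connectivity_matrix(s$count_volumes, s$seed_mask))
  cc2 <- build_ccm(build_connectivity_matrix(rev(s$count_volumes),
                                             s$seed_mask))
  expect_equal(cc1$ccm, cc2$ccm)
})

test_that("proj_thresh turns counts into proportions above the threshold", {
  grid <- c(3L, 1L, 1L)
  aff <- diag(4)
  # voxel 1: (3000,1500,500); voxel 2: total 1000 (sub-threshold);
  # voxel 3: all 5000 samples to one target
  vols <- list(t1 = as_volume(array(c(3000, 400, 5000), grid), aff),
               t2 = as_volume(array(c(1500, 300, 0), grid), aff),
               t3 = as_volume(array(c(500, 300, 0), grid), aff))
  seed <- as_volume(array(TRUE, grid), aff)
  maps <- proj_thresh(vols, seed, threshold = 1250)
  expect_equal(unname(maps$prob[1, ]), c(0.6, 0.3, 0.1))
  expect_equal(unname(maps$prob[2, ]), c(0, 0, 0))
  expect_false(maps$suprathreshold[2])
  expect_equal(unname(maps$prob[3, ]), c(1, 0, 0))
  # a tie with the threshold stays sub-threshold ("above" is strict)
  vols$t1[2] <- 650  # total exactly 1250
  maps2 <- proj_thresh(vols, seed, threshold = 1250)
  expect_false(maps2$suprathreshold[2])
})

test_that("proj_thresh rows sum to one exactly on suprathreshold voxels", {
  coh <- generate_cohort(tiny_config(profile_noise = 0.3, jitter_sd = 0.5,
                                     n_subjects = 2L))
  for (s in coh$subjects) {
    maps <- proj_thresh(s$count_volumes, s$seed_mask, threshold = 1250)
    sums <- rowSums(maps$prob)
    expect_true(all(abs(sums[maps$suprathreshold] - 1) < 1e-9))
    expect_true(all(sums[!maps$suprathreshold] == 0))
    expect_true(all(maps$prob >= 0 & maps$prob <= 1))
  }
})

test_that("regional mean probabilities average voxel values and match the
           planted profile in the noiseless uniform case", {
  grid <- c(2L, 1L, 1L)
  aff <- diag(4)
  vols <- list(t1 = as_volume(array(c(2000, 3000), grid), aff),
               t2 = as_volume(array(c(3000, 2000), grid), aff))
  seed <- as_volume(array(TRUE, grid), aff)
  maps <- proj_thresh(vols, seed, threshold = 1250)
  mu <- mean_probability_per_target(maps, seed)
  expect_equal(unname(mu), c(0.5, 0.5))
  # single-voxel region returns that voxel's probabilities
  one <- as_volume(array(c(TRUE, FALSE), grid), aff)
  expect_equal(unname(mean_probability_per_target(maps, one)), c(0.4, 0.6))
  expect_error(mean_probability_per_target(
    maps, as_volume(array(FALSE, grid), aff)), "empty")

  # phantom, single planted profile, no noise: means within multinomial SE
  p <- c(0.3, 0.3, 0.2, 0.2)
  cfg <- phantom_config(grid_shape = c(8L, 7L, 6L), n_targets = 4L,
                        n_clusters = 1L,
                        cluster_profiles = matrix(p, 1L),
                        profile_noise = 0, jitter_sd = 0,
                        n_subjects = 1L, rng_seed = 9L)
  coh <- generate_cohort(cfg)
  s <- coh$subjects[[1]]
  maps2 <- proj_thresh(s$count_volumes, s$seed_mask)
  mu2 <- mean_probability_per_target(maps2, s$seed_mask)
  n_vox <- sum(s$seed_mask)
  se <- sqrt(p * (1 - p) / (5000 * n_vox))
  expect_true(all(abs(mu2 - p) < 5 * se))
})
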