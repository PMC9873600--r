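# Minimal hand-built parcellation objects for consensus tests.
fake_parc <- function(labels, voxels, k = 3L, affine = diag(4)) {
  structure(list(labels = as.integer(labels), k = as.integer(k),
                 inertia = 0, centers = NULL,
                 voxels = voxels, used = seq_along(labels),
                 affine = affine, subject_id = NULL),
            class = "parcellation")
}

test_that("block-structured CCMs are recovered exactly", {
  # three perfect blocks: within-block correlation 1, between -0.5
  blocks <- rep(1:3, each = 4L)
  r <- outer(blocks, blocks, function(a, b) ifelse(a == b, 1, -0.5))
  cc <- structure(list(ccm = r, used = seq_along(blocks),
                       excluded = tibble::tibble(),
                       voxels = cbind(seq_along(blocks) - 1L, 0L, 0L),
                       affine = diag(4), subject_id = NULL),
                  class = "ccm")
  parc <- kmeans_parcellate(cc, k = 3L, seed = 2, restarts = 5L)
  expect_equal(adjusted_rand_index(parc$labels, blocks), 1)
  expect_equal(sort(unique(parc$labels)), 1:3)
})

test_that("k = 1 yields a single cluster with inertia = total scatter", {
  withr::with_seed(4, x <- matrix(rnorm(40), 8L))
  cc <- structure(list(ccm = x, used = 1:8,
                       excluded = tibble::tibble(),
                       voxels = cbind(0:7, 0L, 0L), affine = diag(4),
                       subject_id = NULL),
                  class = "ccm")
  parc <- kmeans_parcellate(cc, k = 1L, seed = 1, restarts = 2L)
  expect_true(all(parc$labels == 1L))
  scatter <- sum(sweep(x, 2L, colMeans(x), "-")^2)
  expect_equal(parc$inertia, scatter, tolerance = 1e-12)
  expect_error(kmeans_parcellate(cc, k = 9L), "exceeds")
})

test_that("k-means attains the exhaustive-partition optimum on small CCMs", {
  withr::with_seed(31, {
    for (rep in 1:5) {
      n <- sample(8:10, 1L)
      counts <- matrix(rpois(n * 4L, 60), nrow = n)
      r <- oracle_pearson_matrix(counts)
      cc <- structure(list(ccm = r, used = seq_len(n),
                           excluded = tibble::tibble(),
                           voxels = cbind(seq_len(n) - 1L, 0L, 0L),
                           affine = diag(4), subject_id = NULL),
                      class = "ccm")
      parc <- kmeans_parcellate(cc, k = 3L, seed = rep, restarts = 50L)
      expect_equal(parc$inertia, oracle_partition_inertia(r, 3L),
                   tolerance = 1e-9)
    }
  })
})

test_that("label harmonization undoes per-subject label permutations", {
  coh <- clean_cohort(n_subjects = 3L)
  built <- parcellate_cohort(coh)
  parcs <- built$parcs
  # scramble subject 2's labels with a fixed permutation
  perm <- c(3L, 1L, 2L)
  scr <- parcs
  scr[[2]]$labels[scr[[2]]$labels > 0L] <-
    perm[scr[[2]]$labels[scr[[2]]$labels > 0L]]
  harm <- harmonize_labels(scr, built$cms)
  expect_identical(harm[[1]]$labels, harm[[2]]$labels)
  expect_identical(harm[[2]]$labels, harm[[3]]$labels)
  # harmonization is idempotent
  harm2 <- harmonize_labels(harm, built$cms)
  for (i in 1:3) expect_identical(harm2[[i]]$labels, harm[[i]]$labels)
  # anatomical-x reference gives medial -> lateral label order
  harm_x <- harmonize_labels(parcs, reference = "anatomical-x")
  for (p in harm_x) {
    ax <- vapply(1:3, function(c_) {
      w <- voxel_to_world(p$voxels[p$labels == c_, , drop = FALSE],
                          p$affine)
      mean(abs(w[, 1]))
    }, numeric(1))
    expect_true(all(diff(ax) > 0))
  }
})

test_that("assignment cost equals the brute-force permutation minimum", {
  withr::with_seed(8, {
    for (rep in 1:3) {
      cost <- matrix(runif(9), 3L)
      got <- cbparcel:::best_permutation(cost)
      expect_equal(got$cost, oracle_min_assignment(cost), tolerance = 1e-12)
    }
  })
})

test_that("consensus counts, thresholding and overlap resolution follow
           the subject-majority rules", {
  grid <- c(1L, 1L, 1L)
  vox <- cbind(0L, 0L, 0L)
  # 168 subjects, 100 label the voxel as cluster 1: count 100 >= 84
  parcs <- c(
    lapply(1:100, function(i) fake_parc(1L, vox)),
    lapply(1:40, function(i) fake_parc(2L, vox)),
    lapply(1:28, function(i) fake_parc(3L, vox))
  )
  cons <- suppressWarnings(build_consensus(parcs, grid,
                                           threshold_fraction = 0.5))
  expect_equal(as.integer(cons$counts[[1]]), 100L)
  expect_equal(as.integer(cons$final_labels), 1L)

  # n = 4, counts (2, 1, 1): 2 >= ceiling(0.5 * 4) puts it in cluster 1
  parcs4 <- c(lapply(1:2, function(i) fake_parc(1L, vox)),
              list(fake_parc(2L, vox), fake_parc(3L, vox)))
  cons4 <- suppressWarnings(build_consensus(parcs4, grid, 0.5))
  expect_equal(as.integer(cons4$final_labels), 1L)

  # both clusters above threshold: argmax wins (90 vs 95 -> cluster 2)
  two_vox <- cbind(c(0L, 1L), 0L, 0L)
  parcs2 <- c(
    lapply(1:90, function(i) fake_parc(c(1L, 1L), two_vox)),
    lapply(1:95, function(i) fake_parc(c(2L, 1L), two_vox))
  )
  expect_message(
    cons2 <- suppressWarnings(build_consensus(parcs2, c(2L, 1L, 1L), 0.4)),
    "several clusters"
  )
  expect_equal(as.integer(cons2$final_labels)[1], 2L)
})

test_that("consensus is invariant to subject order and clusters disjoint", {
  coh <- generate_cohort(tiny_config(profile_noise = 0.25, jitter_sd = 0.6,
                                     n_subjects = 6L))
  built <- parcellate_cohort(coh)
  harm <- harmonize_labels(built$parcs, built$cms)
  gs <- dim(coh$truth$labels)
  c1 <- suppressWarnings(build_consensus(harm, gs))
  c2 <- suppressWarnings(build_consensus(rev(harm), gs))
  for (k_ in 1:3) expect_identical(c1$counts[[k_]], c2$counts[[k_]])
  expect_identical(c1$final_labels, c2$final_labels)
  # per-voxel counts bounded by the number of subjects; masks disjoint by
  # construction of a single label volume
  total <- Reduce(`+`, c1$counts)
  expect_true(all(total <= length(harm)))
})

test_that("both consensus orders coincide under count-argmax resolution", {
  # when overlaps are resolved by the highest subject count, the cluster
  # with the maximum count passes the threshold whenever any cluster does,
  # so thresholding before or after resolution gives the same labels
  coh <- generate_cohort(tiny_config(profile_noise = 0.3, jitter_sd = 0.8,
                                     n_subjects = 6L))
  built <- parcellate_cohort(coh)
  harm <- harmonize_labels(built$parcs, built$cms)
  gs <- dim(coh$truth$labels)
  a <- suppressMessages(suppressWarnings(
    build_consensus(harm, gs, order = "threshold-then-resolve")))
  b <- suppressMessages(suppressWarnings(
    build_consensus(harm, gs, order = "resolve-then-threshold")))
  expect_identical(a$final_labels, b$final_labels)
})

test_that("raw-fingerprint features can replace CCM rows for clustering", {
  coh <- clean_cohort(n_subjects = 1L)
  s <- coh$subjects[[1]]
  cm <- build_connectivity_matrix(s$count_volumes, s$seed_mask)
  cc <- build_ccm(cm)
  parc <- kmeans_parcellate(cc, seed = 2, restarts = 10L,
                            features = cm$counts[cc$used, ])
  idx <- which(coh$truth$labels > 0L)
  lab <- parcellation_volume(parc, dim(coh$truth$labels))
  expect_equal(adjusted_rand_index(coh$truth$labels[idx], lab[idx]), 1)
})

test_that("pattern classification flags ordered contiguous labelings only", {
  coh <- clean_cohort(n_subjects = 1L)
  lab <- coh$truth$labels
  pat <- classify_pattern(lab)
  expect_true(pat$pattern)
  # interleaved labels break contiguity
  scr <- lab
  idx <- which(scr > 0L)
  scr[idx] <- rep(1:3, length.out = length(idx))
  pat2 <- classify_pattern(scr)
  expect_false(all(pat2$contiguous))
  expect_false(pat2$pattern)
  # reversing the label order breaks the mediolateral sequence
  rev_lab <- lab
  rev_lab[idx] <- 4L - rev_lab[idx]
  pat3 <- classify_pattern(rev_lab)
  expect_false(pat3$pattern)
  expect_true(all(pat3$contiguous))
})

test_that("cluster volumes scale with voxel size", {
  grid <- c(10L, 2L, 2L)
  lab <- array(0L, grid)
  lab[1:10] <- 1L
  expect_equal(cluster_volumes(as_volume(lab, diag(4)))$volume_mm3, 10)
  # 100 voxels at 1.25 mm isotropic
  lab2 <- array(0L, grid)
  lab2[seq_len(40)] <- 1L  # 40 voxels
  aff <- diag(c(1.25, 1.25, 1.25, 1))
  expect_equal(cluster_volumes(as_volume(lab2, aff))$volume_mm3,
               40 * 1.25^3)
  v100 <- cluster_volumes(as_volume(array(1L, c(10L, 10L, 1L)), aff))
  expect_equal(v100$volume_mm3, 195.3125)
  # empty clusters simply do not appear
  expect_equal(nrow(cluster_volumes(as_volume(array(0L, grid), aff))), 0L)
})
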