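# Synthetic tractography phantom: cohorts of probtrackx-like seed-to-target
# streamline-count volumes with planted, spatially contiguous clusters, so
# every downstream stage can be validated against known ground truth.

#' Default target region names
#'
#' The seven behaviourally relevant target regions the parcellation is
#' driven by: nucleus accumbens, brainstem, hippocampus, dorsolateral
#' prefrontal cortex, insula, orbitofrontal cortex and rostral anterior
#' cingulate cortex.
#'
#' @return A character vector of length 7.
#' @export
default_targets <- function() {
  c("NAc", "BS", "HC", "DLPFC", "insula", "OFC", "rACC")
}

#' Default planted cluster connectivity profiles
#'
#' One probability vector over the seven targets per planted cluster, in
#' medial, basal, lateral order. The profiles echo the qualitative pattern
#' expected for the amygdala: the basal cluster is dominated by hippocampal
#' connectivity, the lateral cluster carries relatively more brainstem and
#' DLPFC connectivity, and the medial cluster more insula/OFC.
#'
#' @return A 3 x 7 matrix with rows summing to 1.
#' @export
default_cluster_profiles <- function() {
  p <- rbind(
    medial  = c(NAc = 0.15, BS = 0.05, HC = 0.30, DLPFC = 0.02,
                insula = 0.18, OFC = 0.25, rACC = 0.05),
    basal   = c(NAc = 0.05, BS = 0.08, HC = 0.54, DLPFC = 0.03,
                insula = 0.05, OFC = 0.20, rACC = 0.05),
    lateral = c(NAc = 0.08, BS = 0.21, HC = 0.20, DLPFC = 0.05,
                insula = 0.17, OFC = 0.22, rACC = 0.07)
  )
  colnames(p) <- default_targets()
  p
}

#' Phantom cohort configuration
#'
#' Defines the geometry, sampling depth and variability of a synthetic
#' tractography cohort. Per-voxel target counts are multinomial draws of
#' `samples_per_voxel` streamline samples (5000 by default, matching a
#' standard probtrackx configuration) from the voxel's cluster profile.
#' Inter-subject variability has two knobs: `profile_noise`, the standard
#' deviation of a per-subject, per-voxel logistic-normal perturbation of
#' the cluster profile, and `jitter_sd` (mm), the scale of the spatial
#' misalignment standing in for residual registration error.
#'
#' @param grid_shape Integer vector of 3, the volume grid in voxels.
#' @param voxel_size Isotropic voxel size in mm.
#' @param n_targets Number of target regions.
#' @param n_clusters Number of planted clusters (k).
#' @param samples_per_voxel Streamline samples drawn per seed voxel.
#' @param cluster_profiles `n_clusters` x `n_targets` matrix; each row a
#'   probability vector over targets.
#' @param profile_noise Logistic-normal sd of the per-subject, per-voxel
#'   profile perturbation (0 = noiseless).
#' @param jitter_sd Spatial misalignment scale in mm (0 = perfectly
#'   registered). Realised as a rigid per-subject translation of sd
#'   `jitter_sd` plus a per-voxel positional scatter of sd `jitter_sd / 2`,
#'   so that misregistration both shifts and blurs cluster boundaries.
#' @param n_subjects Cohort size.
#' @param rng_seed Root seed; per-subject streams are derived from it.
#' @param origin World (RAS, mm) coordinate of voxel (0,0,0). The default
#'   centres the seed in the left hemisphere so that the medial-to-lateral
#'   axis runs along increasing |x|.
#' @return A `phantom_config` object (a validated list).
#' @export
phantom_config <- function(grid_shape = c(18L, 14L, 12L),
                           voxel_size = 1.25,
                           n_targets = 7L,
                           n_clusters = 3L,
                           samples_per_voxel = 5000L,
                           cluster_profiles = default_cluster_profiles(),
                           profile_noise = 0.2,
                           jitter_sd = 0.5,
                           n_subjects = 30L,
                           rng_seed = 1L,
                           origin = NULL) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 2L),
            voxel_size > 0, n_targets >= 2L, n_clusters >= 1L,
            samples_per_voxel > 0, n_subjects >= 1L,
            profile_noise >= 0, jitter_sd >= 0)
  cluster_profiles <- as.matrix(cluster_profiles)
  if (nrow(cluster_profiles) != n_clusters ||
      ncol(cluster_profiles) != n_targets) {
    stop("cluster_profiles must be n_clusters x n_targets", call. = FALSE)
  }
  if (any(cluster_profiles < 0) ||
      any(abs(rowSums(cluster_profiles) - 1) > 1e-9)) {
    stop("each cluster profile must be a probability vector summing to 1",
         call. = FALSE)
  }
  if (is.null(colnames(cluster_profiles))) {
    colnames(cluster_profiles) <- paste0("target", seq_len(n_targets))
  }
  if (is.null(origin)) {
    # centre of the grid at (-24, -5, -18) mm: left-hemisphere placement
    centre <- (grid_shape - 1) / 2
    origin <- c(-24, -5, -18) - centre * voxel_size
  }
  affine <- diag(c(voxel_size, voxel_size, voxel_size, 1))
  affine[1:3, 4] <- origin
  structure(
    list(grid_shape = grid_shape, voxel_size = voxel_size,
         n_targets = as.integer(n_targets),
         n_clusters = as.integer(n_clusters),
         samples_per_voxel = as.integer(samples_per_voxel),
         cluster_profiles = cluster_profiles,
         profile_noise = profile_noise, jitter_sd = jitter_sd,
         n_subjects = as.integer(n_subjects),
         rng_seed = as.integer(rng_seed), affine = affine),
    class = "phantom_config"
  )
}

#' @export
print.phantom_config <- function(x, ...) {
  cat("<phantom_config> grid", paste(x$grid_shape, collapse = "x"),
      "@", x$voxel_size, "mm |", x$n_clusters, "clusters,",
      x$n_targets, "targets |", x$samples_per_voxel, "samples/voxel |",
      x$n_subjects, "subjects | noise", x$profile_noise,
      "| jitter", x$jitter_sd, "mm\n")
  invisible(x)
}

# Ellipsoidal seed mask split into n_clusters slabs along the x axis.
# Cluster 1 is the most medial (smallest |x| in world coordinates, i.e.
# closest to the midline), cluster n_clusters the most lateral.
phantom_truth <- function(config) {
  gs <- config$grid_shape
  centre <- (gs - 1) / 2
  semi <- pmax(centre - 1, 1) * c(0.87, 0.95, 0.84)
  ijk <- as.matrix(expand.grid(i = 0:(gs[1] - 1), j = 0:(gs[2] - 1),
                               k = 0:(gs[3] - 1)))
  inside <- ((ijk[, 1] - centre[1]) / semi[1])^2 +
    ((ijk[, 2] - centre[2]) / semi[2])^2 +
    ((ijk[, 3] - centre[3]) / semi[3])^2 <= 1
  labels <- array(0L, dim = gs)
  seed_ijk <- ijk[inside, , drop = FALSE]
  world <- voxel_to_world(seed_ijk, config$affine)
  absx <- abs(world[, 1])
  qs <- stats::quantile(absx, probs = seq_len(config$n_clusters - 1) /
                          config$n_clusters, type = 1)
  lab <- 1L + rowSums(outer(absx, qs, ">"))
  labels[seed_ijk + 1L] <- as.integer(lab)
  centroid_x <- vapply(seq_len(config$n_clusters), function(c_) {
    mean(world[lab == c_, 1])
  }, numeric(1))
  list(labels = as_volume(labels, config$affine),
       seed_mask = as_volume(labels > 0L, config$affine),
       centroid_x = centroid_x, affine = config$affine)
}

# Logistic-normal perturbation of a probability vector: noise on log scale,
# renormalised through softmax.
perturb_profile <- function(p, sd) {
  if (sd == 0) return(p)
  z <- log(p) + rnorm(length(p), 0, sd)
  z <- z - max(z)
  exp(z) / sum(exp(z))
}

#' Generate a synthetic cohort
#'
#' Builds the ground-truth parcellation (an ellipsoidal seed split into
#' spatially contiguous slabs along the medial-to-lateral axis) and draws
#' one synthetic subject per cohort member. Each subject's label field is
#' the ground truth displaced by a random misalignment of scale
#' `jitter_sd`, and each seed voxel's per-target counts are one multinomial
#' draw of `samples_per_voxel` from the voxel's (noise-perturbed) cluster
#' profile. Fully deterministic given `rng_seed`.
#'
#' @param config A [phantom_config()].
#' @return A `phantom_cohort`: list with `truth` (label volume, seed mask,
#'   per-cluster centroid x) and `subjects`, a list of `phantom_subject`
#'   objects each holding `count_volumes` (named list of per-target count
#'   arrays), `seed_mask`, `true_labels` and `subject_id`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  truth <- phantom_truth(config)
  gs <- config$grid_shape
  ijk_all <- as.matrix(expand.grid(i = 0:(gs[1] - 1), j = 0:(gs[2] - 1),
                                   k = 0:(gs[3] - 1)))
  world_all <- voxel_to_world(ijk_all, config$affine)
  tnames <- colnames(config$cluster_profiles)
  subjects <- vector("list", config$n_subjects)
  for (s in seq_len(config$n_subjects)) {
    sid <- sprintf("sub-%03d", s)
    withr::with_seed(subject_seed(config$rng_seed, s), {
      if (config$jitter_sd > 0) {
        shift <- rnorm(3, 0, config$jitter_sd)
        scatter <- matrix(rnorm(3 * nrow(world_all), 0, config$jitter_sd / 2),
                          ncol = 3)
        src <- sweep(world_all, 2, shift, "-") - scatter
      } else {
        src <- world_all
      }
      # nearest-neighbour lookup of the truth label at the source position
      inv <- solve(config$affine)
      vox <- round(cbind(src, 1) %*% t(inv))[, 1:3, drop = FALSE]
      ok <- vox[, 1] >= 0 & vox[, 1] < gs[1] &
        vox[, 2] >= 0 & vox[, 2] < gs[2] &
        vox[, 3] >= 0 & vox[, 3] < gs[3]
      lab <- integer(nrow(vox))
      lab[ok] <- truth$labels[vox[ok, , drop = FALSE] + 1L]
      missing_cluster <- setdiff(seq_len(config$n_clusters), unique(lab))
      if (length(missing_cluster) > 0L) {
        stop("cluster ", missing_cluster[1L], " is empty after jitter for ",
             sid, call. = FALSE)
      }
      labels_s <- array(as.integer(lab), dim = gs)
      seed_idx <- which(lab > 0L)
      counts <- matrix(0L, nrow = nrow(ijk_all), ncol = config$n_targets)
      for (v in seed_idx) {
        p <- perturb_profile(config$cluster_profiles[lab[v], ],
                             config$profile_noise)
        counts[v, ] <- rmultinom(1L, config$samples_per_voxel, p)[, 1L]
      }
      count_volumes <- lapply(seq_len(config$n_targets), function(t_) {
        as_volume(array(counts[, t_], dim = gs), config$affine)
      })
      names(count_volumes) <- tnames
      subjects[[s]] <- structure(
        list(subject_id = sid,
             count_volumes = count_volumes,
             seed_mask = as_volume(labels_s > 0L, config$affine),
             true_labels = as_volume(labels_s, config$affine),
             samples_per_voxel = config$samples_per_voxel,
             affine = config$affine),
        class = "phantom_subject"
      )
    })
  }
  structure(list(truth = truth, subjects = subjects, config = config),
            class = "phantom_cohort")
}

#' @export
print.phantom_cohort <- function(x, ...) {
  cat("<phantom_cohort>", length(x$subjects), "subjects,",
      sum(x$truth$labels > 0), "seed voxels,",
      x$config$n_clusters, "planted clusters\n")
  invisible(x)
}

#' Subject-exclusion arithmetic
#'
#' Cohort accounting for a selection pipeline that drops subjects with
#' incomplete diffusion data and subjects with missing data during
#' tractography classification.
#'
#' @param n_selected Subjects initially selected.
#' @param n_incomplete Subjects excluded for incomplete diffusion data.
#' @param n_missing Subjects excluded for missing tractography outputs.
#' @return The number of analysed subjects.
#' @export
#' @examples
#' apply_exclusions(200, 3, 29) # 168
apply_exclusions <- function(n_selected, n_incomplete, n_missing) {
  stopifnot(n_selected >= 0, n_incomplete >= 0, n_missing >= 0)
  out <- n_selected - n_incomplete - n_missing
  if (out < 0) {
    stop("exclusions (", n_incomplete + n_missing,
         ") exceed the number of selected subjects (", n_selected, ")",
         call. = FALSE)
  }
  out
}

#' Drop subjects with missing or malformed count volumes
#'
#' The cohort-filter counterpart of [apply_exclusions()]: removes subjects
#' whose per-target count volumes are absent, on a different grid, or
#' contain negative/non-finite counts.
#'
#' @param subjects A list of `phantom_subject`-like objects.
#' @param n_targets Expected number of target count volumes.
#' @return A list with `kept` (the retained subjects) and `dropped`
#'   (a tibble of subject_id, reason).
#' @export
drop_incomplete_subjects <- function(subjects, n_targets = 7L) {
  reasons <- character(0)
  ids <- character(0)
  keep <- logical(length(subjects))
  for (i in seq_along(subjects)) {
    s <- subjects[[i]]
    reason <- NULL
    if (is.null(s$count_volumes) || length(s$count_volumes) < n_targets) {
      reason <- "missing target volumes"
    } else {
      dims <- lapply(s$count_volumes, dim)
      if (length(unique(dims)) != 1L) {
        reason <- "grid mismatch across target volumes"
      } else if (any(vapply(s$count_volumes,
                            function(v) any(!is.finite(v)) || any(v < 0),
                            logical(1)))) {
        reason <- "negative or non-finite counts"
      }
    }
    if (is.null(reason)) {
      keep[i] <- TRUE
    } else {
      ids <- c(ids, s$subject_id %||% sprintf("subject %d", i))
      reasons <- c(reasons, reason)
    }
  }
  list(kept = subjects[keep],
       dropped = tibble::tibble(subject_id = ids, reason = reasons))
}
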