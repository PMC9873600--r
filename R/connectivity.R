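# Per-subject connectivity matrices (seed voxel x target streamline counts),
# their cross-correlation matrices (the clustering feature space), and
# proj_thresh-style connection-probability maps.

#' Assemble the seed-voxel x target connectivity matrix
#'
#' Stacks the per-target streamline-count volumes into one row per seed
#' voxel, in deterministic x-fastest scan order (0-based voxel indices).
#' This is the region-level analogue of a probtrackx "matrix 2" output:
#' each row is a seed voxel's connectivity fingerprint over the targets.
#'
#' @param count_volumes Named list of per-target count volumes (3D arrays
#'   sharing grid and affine).
#' @param seed_mask Logical volume selecting seed voxels.
#' @param subject_id Optional identifier carried through downstream tables.
#' @return A `connectivity_matrix`: counts (V x T integer matrix), `voxels`
#'   (V x 3 0-based coordinates), `target_names`, `affine`, `subject_id`.
#' @export
build_connectivity_matrix <- function(count_volumes, seed_mask,
                                      subject_id = NULL) {
  stopifnot(is.list(count_volumes), length(count_volumes) >= 1L)
  check_same_grid(c(count_volumes, list(seed = seed_mask)))
  idx <- which(seed_mask != 0)
  if (length(idx) == 0L) stop("seed mask is empty", call. = FALSE)
  counts <- vapply(count_volumes, function(v) as.numeric(v[idx]),
                   numeric(length(idx)))
  counts <- matrix(counts, nrow = length(idx),
                   dimnames = list(NULL, names(count_volumes)))
  if (any(counts < 0)) stop("negative streamline counts", call. = FALSE)
  voxels <- arrayInd(idx, dim(seed_mask)) - 1L
  structure(
    list(counts = counts, voxels = voxels,
         target_names = names(count_volumes) %||%
           paste0("target", seq_along(count_volumes)),
         affine = attr(seed_mask, "affine") %||%
           attr(count_volumes[[1L]], "affine"),
         subject_id = subject_id),
    class = "connectivity_matrix"
  )
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat("<connectivity_matrix>", nrow(x$counts), "seed voxels x",
      ncol(x$counts), "targets",
      if (!is.null(x$subject_id)) paste0("(", x$subject_id, ")"), "\n")
  invisible(x)
}

#' @method as_tibble connectivity_matrix
#' @export
as_tibble.connectivity_matrix <- function(x, ...) {
  tibble::as_tibble(as.data.frame(x$counts)) |>
    dplyr::mutate(i = x$voxels[, 1], j = x$voxels[, 2], k = x$voxels[, 3],
                  .before = 1)
}

#' Cross-correlation matrix of connectivity fingerprints
#'
#' Pearson correlation between every pair of seed-voxel fingerprints
#' (rows of the connectivity matrix). Voxels whose fingerprint is all zero
#' or constant have no defined correlation; they are excluded and reported
#' rather than imputed.
#'
#' @param cm A [build_connectivity_matrix()] result.
#' @param normalize_rows If TRUE, fingerprints are divided by their row sum
#'   before correlating (default FALSE: raw counts).
#' @return A `ccm` object: `ccm` (V_used x V_used symmetric matrix with
#'   unit diagonal), `used` (row indices into `cm`), `excluded` (tibble of
#'   index, reason), plus voxel coordinates and affine for the used rows.
#' @export
build_ccm <- function(cm, normalize_rows = FALSE) {
  stopifnot(inherits(cm, "connectivity_matrix"))
  x <- cm$counts
  if (normalize_rows) {
    rs <- rowSums(x)
    x[rs > 0, ] <- x[rs > 0, , drop = FALSE] / rs[rs > 0]
  }
  zero <- rowSums(abs(x)) == 0
  const <- !zero & apply(x, 1L, function(r) max(r) == min(r))
  usable <- !zero & !const
  if (sum(usable) < 2L) {
    stop("need at least 2 usable (non-constant) fingerprints, got ",
         sum(usable), call. = FALSE)
  }
  excluded <- tibble::tibble(
    index = which(!usable),
    reason = ifelse(zero[!usable], "all-zero fingerprint",
                    "constant fingerprint")
  )
  if (nrow(excluded) > 0L) {
    message("build_ccm: excluded ", nrow(excluded),
            " voxel(s) with zero/constant fingerprints")
  }
  r <- stats::cor(t(x[usable, , drop = FALSE]))
  r <- (r + t(r)) / 2
  diag(r) <- 1
  structure(
    list(ccm = r, used = which(usable), excluded = excluded,
         voxels = cm$voxels, affine = cm$affine,
         subject_id = cm$subject_id),
    class = "ccm"
  )
}

#' @export
print.ccm <- function(x, ...) {
  cat("<ccm>", nrow(x$ccm), "x", ncol(x$ccm), "voxel correlations,",
      nrow(x$excluded), "excluded\n")
  invisible(x)
}

#' Connection-probability maps (proj_thresh emulation)
#'
#' Converts per-target streamline counts into per-voxel connection
#' probabilities: for every seed voxel whose total sample count exceeds
#' `threshold`, each target's value becomes count / total (a proportion in
#' \[0, 1\] summing to 1 over targets); voxels at or below the threshold
#' are flagged sub-threshold and set to 0 everywhere.
#'
#' @param count_volumes Named list of per-target count volumes.
#' @param seed_mask Logical seed volume.
#' @param threshold Minimum total samples (strictly exceeded); default 1250.
#' @param subject_id Optional identifier.
#' @return A `conn_prob_maps` object: `prob` (V x T matrix), `voxels`,
#'   `suprathreshold` (logical V), `target_names`, `affine`.
#' @export
proj_thresh <- function(count_volumes, seed_mask, threshold = 1250,
                        subject_id = NULL) {
  stopifnot(threshold >= 0)
  cm <- build_connectivity_matrix(count_volumes, seed_mask,
                                  subject_id = subject_id)
  totals <- rowSums(cm$counts)
  supra <- totals > threshold
  prob <- matrix(0, nrow = nrow(cm$counts), ncol = ncol(cm$counts),
                 dimnames = list(NULL, cm$target_names))
  prob[supra, ] <- cm$counts[supra, , drop = FALSE] / totals[supra]
  structure(
    list(prob = prob, voxels = cm$voxels, suprathreshold = supra,
         totals = totals, threshold = threshold,
         target_names = cm$target_names, affine = cm$affine,
         grid_shape = dim(seed_mask), subject_id = subject_id),
    class = "conn_prob_maps"
  )
}

#' @export
print.conn_prob_maps <- function(x, ...) {
  cat("<conn_prob_maps>", nrow(x$prob), "seed voxels x",
      ncol(x$prob), "targets;", sum(!x$suprathreshold),
      "sub-threshold (threshold", x$threshold, ")\n")
  invisible(x)
}

#' Expand one target's probability map to a volume
#'
#' @param maps A [proj_thresh()] result.
#' @param target Target name or column index.
#' @return A 3D array (0 outside the seed) with the affine attached.
#' @export
probability_volume <- function(maps, target) {
  stopifnot(inherits(maps, "conn_prob_maps"))
  vol <- array(0, dim = maps$grid_shape)
  idx <- maps$voxels + 1L
  vol[idx] <- maps$prob[, target]
  as_volume(vol, maps$affine)
}

#' Mean connection probability per target over a region
#'
#' Arithmetic mean, over the voxels of `region_mask`, of each target's
#' connection-probability map (sub-threshold voxels contribute 0).
#'
#' @param maps A [proj_thresh()] result.
#' @param region_mask Logical volume; must lie within the seed voxels of
#'   `maps` unless `allow_partial` is set.
#' @param allow_partial If TRUE, region voxels outside the subject's seed
#'   coverage are dropped from the mean instead of raising an error (used
#'   when a group-level cluster mask is applied to imperfectly aligned
#'   subjects).
#' @return Named numeric vector over targets.
#' @export
mean_probability_per_target <- function(maps, region_mask,
                                        allow_partial = FALSE) {
  stopifnot(inherits(maps, "conn_prob_maps"))
  idx <- which(region_mask != 0)
  if (length(idx) == 0L) stop("region mask is empty", call. = FALSE)
  lin <- maps$voxels[, 1] + 1L +
    maps$voxels[, 2] * maps$grid_shape[1] +
    maps$voxels[, 3] * maps$grid_shape[1] * maps$grid_shape[2]
  rows <- match(idx, lin)
  if (anyNA(rows)) {
    if (!allow_partial) {
      stop("region mask extends outside the seed mask", call. = FALSE)
    }
    rows <- rows[!is.na(rows)]
    if (length(rows) == 0L) {
      stop("region mask does not overlap the seed mask", call. = FALSE)
    }
  }
  colMeans(maps$prob[rows, , drop = FALSE])
}

#' Cohort-mean connection probability per target
#'
#' Per-subject means over a region (see [mean_probability_per_target()])
#' averaged across subjects — the whole-seed analogue of the per-cluster
#' probability summaries.
#'
#' @param maps_list List of [proj_thresh()] results, one per subject.
#' @param region_mask Logical volume.
#' @param allow_partial Passed to [mean_probability_per_target()]; set when
#'   the region is a group-level mask and subjects are imperfectly aligned.
#' @return A tibble with one row per target: `target`, `mean_probability`,
#'   `se` (standard error over subjects).
#' @export
cohort_mean_probability <- function(maps_list, region_mask,
                                    allow_partial = TRUE) {
  per_subject <- vapply(maps_list, mean_probability_per_target,
                        numeric(ncol(maps_list[[1L]]$prob)),
                        region_mask = region_mask,
                        allow_partial = allow_partial)
  per_subject <- matrix(per_subject, ncol = length(maps_list))
  tibble::tibble(
    target = maps_list[[1L]]$target_names,
    mean_probability = rowMeans(per_subject),
    se = apply(per_subject, 1L, sd) / sqrt(ncol(per_subject))
  )
}
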