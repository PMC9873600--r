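# Subject-level k-means parcellation of the CCM, cross-subject label
# harmonization, thresholded consensus maps, and the descriptive
# post-hoc checks (mediolateral pattern, contiguity, cluster volumes).

# k-means++ seeding: first centre uniform, subsequent centres drawn with
# probability proportional to the squared distance to the nearest chosen
# centre.
kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  centres <- integer(k)
  centres[1L] <- sample.int(n, 1L)
  if (k > 1L) {
    d2 <- rowSums(sweep(x, 2L, x[centres[1L], ], "-")^2)
    for (c_ in 2:k) {
      if (all(d2 == 0)) {
        centres[c_] <- sample.int(n, 1L)
      } else {
        centres[c_] <- sample.int(n, 1L, prob = d2)
      }
      d2 <- pmin(d2, rowSums(sweep(x, 2L, x[centres[c_], ], "-")^2))
    }
  }
  x[centres, , drop = FALSE]
}

#' k-means parcellation of a cross-correlation matrix
#'
#' Clusters seed voxels by the similarity of their connectivity profiles:
#' the feature vector of a voxel is its row of the CCM (its correlation to
#' every other seed voxel). Lloyd's algorithm with k-means++ initialization
#' and squared-Euclidean distance, best of `restarts` restarts by inertia
#' (total within-cluster sum of squares). Restarts that collapse to an
#' empty cluster are re-seeded and noted.
#'
#' @param ccm A [build_ccm()] result.
#' @param k Number of clusters (default 3, reflecting the gross nuclear
#'   organisation of the amygdala).
#' @param seed Optional RNG seed making the parcellation deterministic.
#' @param restarts Number of random restarts.
#' @param features Optional alternative feature matrix (one row per usable
#'   CCM voxel), e.g. raw connectivity fingerprints; by default the rows
#'   of the CCM itself are clustered.
#' @return A `parcellation`: `labels` (one per connectivity-matrix voxel;
#'   0 for voxels excluded from the CCM), `k`, `inertia`, `centers`,
#'   `voxels`, `affine`, `subject_id`.
#' @export
kmeans_parcellate <- function(ccm, k = 3L, seed = NULL, restarts = 20L,
                              features = NULL) {
  stopifnot(inherits(ccm, "ccm"), k >= 1L, restarts >= 1L)
  x <- features %||% ccm$ccm
  stopifnot(nrow(x) == nrow(ccm$ccm))
  if (k > nrow(x)) {
    stop("k = ", k, " exceeds the number of usable voxels (", nrow(x), ")",
         call. = FALSE)
  }
  if (!is.null(seed)) withr::local_seed(seed)
  best <- NULL
  reseeded <- 0L
  for (r in seq_len(restarts)) {
    fit <- NULL
    attempt <- 0L
    while (is.null(fit) && attempt < 10L) {
      attempt <- attempt + 1L
      init <- kmeanspp_init(x, k)
      fit <- tryCatch(
        suppressWarnings(
          stats::kmeans(x, centers = init, iter.max = 100L,
                        algorithm = "Lloyd")
        ),
        error = function(e) NULL
      )
      if (is.null(fit)) reseeded <- reseeded + 1L
    }
    if (is.null(fit)) next
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  if (is.null(best)) stop("k-means failed on all restarts", call. = FALSE)
  if (reseeded > 0L) {
    message("kmeans_parcellate: re-seeded ", reseeded,
            " restart(s) after empty-cluster collapse")
  }
  labels <- integer(nrow(ccm$voxels))
  labels[ccm$used] <- as.integer(best$cluster)
  structure(
    list(labels = labels, k = as.integer(k),
         inertia = unname(best$tot.withinss), centers = best$centers,
         voxels = ccm$voxels, used = ccm$used, affine = ccm$affine,
         subject_id = ccm$subject_id),
    class = "parcellation"
  )
}

#' @export
print.parcellation <- function(x, ...) {
  cat("<parcellation> k =", x$k, "over", length(x$labels), "voxels",
      sprintf("(inertia %.4g)", x$inertia),
      if (!is.null(x$subject_id)) paste0("[", x$subject_id, "]"), "\n")
  invisible(x)
}

#' Render a parcellation's labels as a volume
#'
#' @param parc A `parcellation`.
#' @param grid_shape Grid dimensions of the underlying volume.
#' @return An integer label array (0 = background/unlabeled).
#' @export
parcellation_volume <- function(parc, grid_shape) {
  vol <- array(0L, dim = grid_shape)
  vol[parc$voxels + 1L] <- parc$labels
  as_volume(vol, parc$affine)
}

# Cluster-mean connectivity fingerprints (row-normalised to proportions so
# that the matching is invariant to sampling depth).
cluster_fingerprints <- function(parc, cm) {
  x <- cm$counts
  rs <- rowSums(x)
  x[rs > 0, ] <- x[rs > 0, , drop = FALSE] / rs[rs > 0]
  t(vapply(seq_len(parc$k), function(c_) {
    colMeans(x[parc$labels == c_, , drop = FALSE])
  }, numeric(ncol(x))))
}

# Mean absolute world-x (distance from the midline) per cluster.
cluster_abs_x <- function(parc) {
  world <- voxel_to_world(parc$voxels, parc$affine)
  vapply(seq_len(parc$k), function(c_) {
    mean(abs(world[parc$labels == c_, 1]))
  }, numeric(1))
}

#' Harmonize cluster labels across subjects
#'
#' k-means labels are arbitrary per subject; before consensus they must be
#' made to correspond. With `reference = "fingerprint"` (default), each
#' subject's cluster-mean connectivity fingerprints are matched to a
#' cohort-median reference by minimum-cost one-to-one assignment
#' (exhaustive over the k! permutations, which is the exact Hungarian
#' solution at this size); ties go to the lowest label first. With
#' `reference = "anatomical-x"`, clusters are instead ranked by the
#' distance of their centroid from the midline (medial to lateral).
#'
#' @param parcellations List of `parcellation` objects sharing `k`.
#' @param conn_matrices List of matching `connectivity_matrix` objects
#'   (required for `"fingerprint"`).
#' @param reference `"fingerprint"` or `"anatomical-x"`.
#' @return The list of parcellations with labels permuted into a common
#'   scheme; the applied permutations are attached as the `"permutations"`
#'   attribute.
#' @export
harmonize_labels <- function(parcellations, conn_matrices = NULL,
                             reference = c("fingerprint", "anatomical-x")) {
  reference <- match.arg(reference)
  ks <- vapply(parcellations, `[[`, integer(1), "k")
  stopifnot(length(unique(ks)) == 1L)
  k <- ks[1L]
  relabel <- function(parc, perm) {
    # perm[c] = new label of old cluster c
    new_labels <- parc$labels
    pos <- parc$labels > 0L
    new_labels[pos] <- perm[parc$labels[pos]]
    parc$labels <- new_labels
    parc$centers <- parc$centers[order(perm), , drop = FALSE]
    parc
  }
  if (reference == "anatomical-x") {
    perms <- lapply(parcellations, function(p) {
      order(order(cluster_abs_x(p)))  # rank: most medial -> 1
    })
  } else {
    if (is.null(conn_matrices) ||
        length(conn_matrices) != length(parcellations)) {
      stop("fingerprint harmonization needs one connectivity matrix per ",
           "parcellation", call. = FALSE)
    }
    fps <- purrr::map2(parcellations, conn_matrices, cluster_fingerprints)
    # provisional medial-to-lateral slot order gives a label-free frame in
    # which to take the cohort-median reference fingerprints
    prov <- lapply(parcellations, function(p) order(cluster_abs_x(p)))
    ref <- vapply(seq_len(k), function(slot) {
      apply(vapply(seq_along(fps), function(s) {
        fps[[s]][prov[[s]][slot], ]
      }, numeric(ncol(fps[[1L]]))), 1L, median)
    }, numeric(ncol(fps[[1L]])))
    ref <- t(ref)  # k x T
    n_ties <- 0L
    perms <- lapply(seq_along(fps), function(s) {
      cost <- as.matrix(stats::dist(rbind(fps[[s]], ref)))^2
      cost <- cost[seq_len(k), k + seq_len(k), drop = FALSE]
      a <- best_permutation(cost)
      if (a$tied) n_ties <<- n_ties + 1L
      a$perm
    })
    if (n_ties > 0L) {
      message("harmonize_labels: ", n_ties,
              " tied assignment(s) broken lowest-label-first")
    }
  }
  out <- purrr::map2(parcellations, perms, relabel)
  attr(out, "permutations") <- perms
  out
}

#' Cross-subject consensus cluster maps
#'
#' For each harmonized cluster, counts at every voxel the number of
#' subjects carrying that label there, then thresholds: a voxel is
#' eligible for cluster c when `count_c >= ceiling(threshold_fraction *
#' n_subjects)`; voxels eligible for several clusters go to the cluster
#' with the highest count (ties to the lowest cluster index, counted and
#' reported).
#'
#' @param parcellations Harmonized `parcellation` list on a common grid.
#' @param grid_shape Common grid dimensions.
#' @param threshold_fraction Consensus threshold (default 0.5, i.e. at
#'   least half the subjects).
#' @param order `"threshold-then-resolve"` (default): a voxel is eligible
#'   for every cluster whose count passes the threshold and overlaps go to
#'   the highest count. `"resolve-then-threshold"`: the voxel is first
#'   assigned to its highest-count cluster, then kept only if that count
#'   passes the threshold (a voxel whose runner-up cluster passes while
#'   the winner does not stays unlabeled under this order).
#' @return A `consensus_map`: `counts` (list of per-cluster count arrays),
#'   `final_labels` (integer array, 0 = no consensus), `n_subjects`,
#'   `threshold_fraction`, `affine`.
#' @export
build_consensus <- function(parcellations, grid_shape,
                            threshold_fraction = 0.5,
                            order = c("threshold-then-resolve",
                                      "resolve-then-threshold")) {
  order <- match.arg(order)
  stopifnot(length(parcellations) >= 1L,
            threshold_fraction > 0, threshold_fraction <= 1)
  k <- parcellations[[1L]]$k
  n <- length(parcellations)
  counts <- lapply(seq_len(k), function(c_) array(0L, dim = grid_shape))
  for (p in parcellations) {
    stopifnot(p$k == k)
    lin <- p$voxels[, 1] + 1L + p$voxels[, 2] * grid_shape[1] +
      p$voxels[, 3] * grid_shape[1] * grid_shape[2]
    for (c_ in seq_len(k)) {
      at <- lin[p$labels == c_]
      counts[[c_]][at] <- counts[[c_]][at] + 1L
    }
  }
  thr <- ceiling(threshold_fraction * n)
  cnt_mat <- matrix(vapply(counts, as.integer, integer(prod(grid_shape))),
                    nrow = prod(grid_shape))
  eligible <- cnt_mat >= thr
  final <- integer(prod(grid_shape))
  if (order == "threshold-then-resolve") {
    any_el <- rowSums(eligible) > 0L
    if (any(any_el)) {
      masked <- cnt_mat
      masked[!eligible] <- -1L
      final[any_el] <- max.col(masked[any_el, , drop = FALSE],
                               ties.method = "first")
      n_over <- sum(rowSums(eligible[any_el, , drop = FALSE]) > 1L)
      if (n_over > 0L) {
        message("build_consensus: ", n_over,
                " voxel(s) passed the threshold for several clusters; ",
                "assigned to the highest count")
      }
    }
  } else {
    any_lab <- rowSums(cnt_mat) > 0L
    if (any(any_lab)) {
      win <- max.col(cnt_mat[any_lab, , drop = FALSE],
                     ties.method = "first")
      keep <- cnt_mat[cbind(which(any_lab), win)] >= thr
      final[which(any_lab)[keep]] <- win[keep]
    }
  }
  empty <- setdiff(seq_len(k), unique(final[final > 0L]))
  if (length(empty) > 0L) {
    warning("consensus cluster(s) ", paste(empty, collapse = ", "),
            " are empty after thresholding", call. = FALSE)
  }
  affine <- parcellations[[1L]]$affine
  structure(
    list(counts = lapply(counts, as_volume, affine = affine),
         final_labels = as_volume(array(final, dim = grid_shape), affine),
         n_subjects = n, threshold_fraction = threshold_fraction,
         order = order, k = k, affine = affine),
    class = "consensus_map"
  )
}

#' @export
print.consensus_map <- function(x, ...) {
  sizes <- vapply(seq_len(x$k), function(c_) sum(x$final_labels == c_),
                  integer(1))
  cat("<consensus_map>", x$n_subjects, "subjects, threshold",
      x$threshold_fraction, "| final cluster sizes:",
      paste(sizes, collapse = "/"), "voxels\n")
  invisible(x)
}

#' Mediolateral pattern classification
#'
#' Checks whether a labeling shows the expected medial-to-lateral cluster
#' arrangement: per hemisphere, cluster centroids ordered by increasing
#' distance from the midline (|world x|) must follow increasing cluster
#' index, and every cluster must form a single 6-connected component.
#'
#' @param labels Integer label volume (0 = background) with an affine, or
#'   a `parcellation` plus `grid_shape`.
#' @param affine Optional 4x4 affine (defaults to the attribute).
#' @param grid_shape Needed only when `labels` is a `parcellation`.
#' @return A list: `pattern` (TRUE when ordering and contiguity both
#'   hold), `sequence` (cluster ids from medial to lateral, per
#'   hemisphere), `contiguous` (per cluster), `centroid_abs_x`.
#' @export
classify_pattern <- function(labels, affine = NULL, grid_shape = NULL) {
  if (inherits(labels, "parcellation")) {
    stopifnot(!is.null(grid_shape))
    labels <- parcellation_volume(labels, grid_shape)
  }
  aff <- affine %||% attr(labels, "affine")
  stopifnot(!is.null(aff))
  ids <- sort(unique(labels[labels > 0L]))
  if (length(ids) < 2L) stop("need at least 2 clusters", call. = FALSE)
  idx <- which(labels > 0L)
  coords <- arrayInd(idx, dim(labels)) - 1L
  world <- voxel_to_world(coords, aff)
  lab <- labels[idx]
  hemi <- ifelse(world[, 1] < 0, "left", "right")
  sequences <- list()
  ordered_ok <- TRUE
  for (h in unique(hemi)) {
    sel <- hemi == h
    present <- sort(unique(lab[sel]))
    if (length(present) < 2L) next
    cab <- vapply(present, function(c_) {
      mean(abs(world[sel & lab == c_, 1]))
    }, numeric(1))
    seq_h <- present[order(cab)]
    sequences[[h]] <- seq_h
    ordered_ok <- ordered_ok && identical(seq_h, sort(present))
  }
  contiguous <- vapply(ids, function(c_) {
    comp <- connected_components6(coords[lab == c_, , drop = FALSE])
    length(unique(comp)) == 1L
  }, logical(1))
  centroid_abs_x <- vapply(ids, function(c_) mean(abs(world[lab == c_, 1])),
                           numeric(1))
  list(pattern = ordered_ok && all(contiguous),
       sequence = sequences,
       contiguous = stats::setNames(contiguous, paste0("cluster", ids)),
       centroid_abs_x = stats::setNames(centroid_abs_x,
                                        paste0("cluster", ids)))
}

#' Cluster volumes in cubic millimetres
#'
#' @param labels Integer label volume with an affine.
#' @param affine Optional 4x4 affine overriding the attribute.
#' @return A tibble: `cluster`, `n_voxels`, `volume_mm3`.
#' @export
cluster_volumes <- function(labels, affine = NULL) {
  aff <- affine %||% attr(labels, "affine")
  stopifnot(!is.null(aff))
  vv <- voxel_volume_mm3(aff)
  ids <- sort(unique(labels[labels > 0L]))
  n <- vapply(ids, function(c_) sum(labels == c_), integer(1))
  tibble::tibble(cluster = as.integer(ids), n_voxels = n,
                 volume_mm3 = n * vv)
}
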