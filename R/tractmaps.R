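# Group tract-map algebra for cluster-seeded tractograms:
# normalize -> threshold -> binarize -> sum across subjects -> final
# subject-count threshold.

#' Normalize a visitation map to its maximum
#'
#' Divides a nonnegative visitation/probability volume by its maximum so
#' that values lie in \[0, 1\]; idempotent.
#'
#' @param m A nonnegative numeric array (or vector).
#' @return The rescaled map, same shape, max exactly 1.
#' @export
normalize_map <- function(m) {
  stopifnot(all(is.finite(m)), all(m >= 0))
  mx <- max(m)
  if (mx <= 0) stop("cannot normalize an all-zero map", call. = FALSE)
  out <- m / mx
  attributes(out) <- attributes(m)
  out
}

#' Threshold and binarize a normalized map
#'
#' @param m A map with values in \[0, 1\].
#' @param q Threshold (default 0.95); voxels with value `>= q` become 1,
#'   all others 0.
#' @return An integer 0/1 array of the same shape.
#' @export
threshold_binarize <- function(m, q = 0.95) {
  if (!is.numeric(q) || length(q) != 1L || q < 0 || q > 1) {
    stop("q must be a single value in [0, 1]", call. = FALSE)
  }
  out <- array(as.integer(m >= q), dim = dim(m) %||% length(m))
  if (!is.null(attr(m, "affine"))) attr(out, "affine") <- attr(m, "affine")
  out
}

#' Sum binarized maps across subjects
#'
#' Voxelwise integer sum of per-subject binary maps; optionally applies a
#' final group-level threshold on the subject count.
#'
#' @param binaries List of 0/1 arrays on the same grid.
#' @param min_subjects Optional final threshold: the mask keeps voxels
#'   present in at least this many subjects.
#' @return A `group_tract_map`: `counts` (integer array, values
#'   0..n_subjects), `n_subjects`, `min_subjects`, and `mask` when
#'   `min_subjects` is given.
#' @export
group_sum <- function(binaries, min_subjects = NULL) {
  stopifnot(length(binaries) >= 1L)
  check_same_grid(binaries)
  counts <- Reduce(`+`, binaries)
  counts <- array(as.integer(counts), dim = dim(binaries[[1L]]))
  if (!is.null(attr(binaries[[1L]], "affine"))) {
    attr(counts, "affine") <- attr(binaries[[1L]], "affine")
  }
  mask <- NULL
  if (!is.null(min_subjects)) {
    stopifnot(min_subjects >= 0)
    mask <- counts >= min_subjects
    if (!is.null(attr(counts, "affine"))) {
      attr(mask, "affine") <- attr(counts, "affine")
    }
  }
  structure(
    list(counts = counts, n_subjects = length(binaries),
         min_subjects = min_subjects, mask = mask),
    class = "group_tract_map"
  )
}

#' @export
print.group_tract_map <- function(x, ...) {
  cat("<group_tract_map>", x$n_subjects, "subjects; max count",
      max(x$counts),
      if (!is.null(x$min_subjects))
        paste0("; mask >= ", x$min_subjects, ": ", sum(x$mask), " voxels"),
      "\n")
  invisible(x)
}

#' Full per-subject tract-map reduction
#'
#' Convenience wrapper chaining [normalize_map()], [threshold_binarize()]
#' and [group_sum()] over a list of per-subject visitation maps.
#'
#' @param maps List of nonnegative visitation volumes (same grid).
#' @param q Normalized-value threshold (default 0.95).
#' @param min_subjects Final group-level subject-count threshold.
#' @return A `group_tract_map`.
#' @export
group_tract_map <- function(maps, q = 0.95, min_subjects = NULL) {
  binaries <- lapply(maps, function(m) threshold_binarize(normalize_map(m), q))
  group_sum(binaries, min_subjects = min_subjects)
}
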