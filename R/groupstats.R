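# Subject x cluster x target connection-probability profiles and the
# one-way ANOVA (with Bonferroni-corrected pairwise post-hocs) comparing
# clusters per target region.

#' Build the subject x cluster x target profile table
#'
#' For every subject, cluster and target: the mean of the subject's
#' connection-probability map over the voxels of the final consensus
#' cluster. These subject-level cluster means are the observational unit
#' of the downstream ANOVA (voxels within a cluster are not independent).
#'
#' @param maps_list List of [proj_thresh()] results, one per subject.
#' @param final_labels Consensus label volume (e.g.
#'   `consensus$final_labels`), on the same grid as the maps.
#' @param hemisphere Hemisphere tag for the rows; `"auto"` derives it per
#'   cluster from the sign of the cluster centroid's world x.
#' @return A `cluster_profile_tbl` tibble: `subject_id`, `hemisphere`,
#'   `cluster`, `target`, `probability`.
#' @export
build_profile_table <- function(maps_list, final_labels,
                                hemisphere = "auto") {
  stopifnot(length(maps_list) >= 1L)
  ids <- sort(unique(final_labels[final_labels > 0L]))
  if (length(ids) == 0L) stop("no clusters in final_labels", call. = FALSE)
  aff <- attr(final_labels, "affine") %||% maps_list[[1L]]$affine
  rows <- list()
  skipped <- integer(0)
  for (c_ in ids) {
    mask <- final_labels == c_
    if (!any(mask)) {
      skipped <- c(skipped, c_)
      next
    }
    if (identical(hemisphere, "auto")) {
      coords <- arrayInd(which(mask), dim(final_labels)) - 1L
      hx <- mean(voxel_to_world(coords, aff)[, 1])
      hemi <- if (hx < 0) "left" else "right"
    } else {
      hemi <- hemisphere
    }
    for (s in seq_along(maps_list)) {
      m <- maps_list[[s]]
      mu <- mean_probability_per_target(m, mask, allow_partial = TRUE)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        subject_id = m$subject_id %||% sprintf("sub-%03d", s),
        hemisphere = hemi,
        cluster = as.integer(c_),
        target = m$target_names,
        probability = unname(mu)
      )
    }
  }
  if (length(skipped) > 0L) {
    warning("empty cluster(s) omitted from the profile table: ",
            paste(skipped, collapse = ", "), call. = FALSE)
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("cluster_profile_tbl", class(out))
  out
}

#' One-way ANOVA comparing clusters for one target
#'
#' Fixed-effects one-way ANOVA of the subject-level cluster means for one
#' target region (and hemisphere), followed by pairwise two-sided pooled-sd
#' t tests with Bonferroni correction over the cluster pairs. Degenerate
#' inputs with zero within-group variance yield F = 0 (equal means) or
#' F = Inf (unequal means) rather than NaN.
#'
#' @param table A [build_profile_table()] tibble.
#' @param target Target region name.
#' @param hemisphere Optional hemisphere filter.
#' @param alpha Significance level applied to the corrected p values.
#' @return A `cluster_anova` object; see [tidy()] and [glance()] methods.
#' @export
anova_per_target <- function(table, target, hemisphere = NULL,
                             alpha = 0.05) {
  dat <- dplyr::filter(table, .data$target == !!target)
  if (!is.null(hemisphere)) {
    dat <- dplyr::filter(dat, .data$hemisphere == !!hemisphere)
  }
  groups <- split(dat$probability, dat$cluster)
  if (length(groups) < 2L || any(lengths(groups) < 2L)) {
    stop("need at least 2 clusters with at least 2 subjects each",
         call. = FALSE)
  }
  k <- length(groups)
  n <- lengths(groups)
  N <- sum(n)
  means <- vapply(groups, mean, numeric(1))
  grand <- sum(unlist(groups)) / N
  ss_between <- sum(n * (means - grand)^2)
  ss_within <- sum(vapply(groups, function(g) sum((g - mean(g))^2),
                          numeric(1)))
  df1 <- k - 1L
  df2 <- N - k
  if (ss_within <= 0) {
    f_stat <- if (ss_between <= 1e-15 * max(1, grand^2)) 0 else Inf
    p <- if (is.finite(f_stat)) 1 else 0
  } else {
    ow <- stats::oneway.test(probability ~ factor(cluster), data = dat,
                             var.equal = TRUE)
    f_stat <- unname(ow$statistic)
    p <- unname(ow$p.value)
  }
  pairs <- combn(names(groups), 2L)
  m_comp <- ncol(pairs)
  mse <- if (df2 > 0) ss_within / df2 else 0
  posthoc <- purrr::map_dfr(seq_len(m_comp), function(i) {
    a <- pairs[1L, i]; b <- pairs[2L, i]
    ga <- groups[[a]]; gb <- groups[[b]]
    diff <- mean(ga) - mean(gb)
    # pooled variance from the two groups
    dfp <- length(ga) + length(gb) - 2L
    sp2 <- (sum((ga - mean(ga))^2) + sum((gb - mean(gb))^2)) / dfp
    if (sp2 <= 0) {
      p_raw <- if (abs(diff) <= 1e-15) 1 else 0
      t_stat <- if (abs(diff) <= 1e-15) 0 else Inf * sign(diff)
    } else {
      t_stat <- diff / sqrt(sp2 * (1 / length(ga) + 1 / length(gb)))
      p_raw <- 2 * pt(-abs(t_stat), df = dfp)
    }
    tibble::tibble(
      cluster_a = as.integer(a), cluster_b = as.integer(b),
      mean_difference = diff, statistic = t_stat, df = dfp,
      p_value = p_raw,
      p_bonferroni = pmin(1, p_raw * m_comp)
    )
  })
  structure(
    list(target = target,
         hemisphere = hemisphere %||% unique(dat$hemisphere),
         statistic = f_stat, df_between = df1, df_within = df2,
         p_value = p, group_means = means, group_n = n,
         posthoc = posthoc, alpha = alpha,
         n_comparisons = m_comp),
    class = "cluster_anova"
  )
}

#' @export
print.cluster_anova <- function(x, ...) {
  cat(sprintf(
    "<cluster_anova> %s (%s): F(%d, %d) = %.4g, p = %.3g\n",
    x$target, paste(x$hemisphere, collapse = "/"),
    x$df_between, x$df_within, x$statistic, x$p_value))
  sig <- x$posthoc$p_bonferroni < x$alpha
  if (any(sig)) {
    cat("  significant pairs (Bonferroni):",
        paste(sprintf("%d-%d", x$posthoc$cluster_a[sig],
                      x$posthoc$cluster_b[sig]), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @rdname anova_per_target
#' @param x A `cluster_anova` object.
#' @param ... Unused.
#' @method tidy cluster_anova
#' @export
tidy.cluster_anova <- function(x, ...) {
  dplyr::mutate(x$posthoc, target = x$target,
                hemisphere = paste(x$hemisphere, collapse = "/"),
                .before = 1)
}

#' @rdname anova_per_target
#' @method glance cluster_anova
#' @export
glance.cluster_anova <- function(x, ...) {
  tibble::tibble(
    target = x$target,
    hemisphere = paste(x$hemisphere, collapse = "/"),
    statistic = x$statistic, df_between = x$df_between,
    df_within = x$df_within, p_value = x$p_value,
    n_significant_pairs = sum(x$posthoc$p_bonferroni < x$alpha)
  )
}

#' ANOVA over all targets (and hemispheres) of a profile table
#'
#' @param table A [build_profile_table()] tibble.
#' @param alpha Significance level after Bonferroni correction.
#' @return A tibble with one row per target x hemisphere (the [glance()]
#'   of each fit) and the fitted `cluster_anova` objects in a `fit`
#'   list-column.
#' @export
anova_all_targets <- function(table, alpha = 0.05) {
  cells <- dplyr::distinct(table, .data$target, .data$hemisphere)
  fits <- purrr::map(seq_len(nrow(cells)), function(i) {
    anova_per_target(table, cells$target[i],
                     hemisphere = cells$hemisphere[i], alpha = alpha)
  })
  out <- purrr::map_dfr(fits, glance)
  out$fit <- fits
  out
}
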