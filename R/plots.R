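# ggplot2 views of the main result types.

#' Bar plot of per-cluster connection probabilities
#'
#' Cluster x target mean connection probabilities (bars) with standard
#' errors over subjects, the standard way these per-cluster profiles are
#' presented.
#'
#' @param object A `cluster_profile_tbl` from [build_profile_table()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cluster_profile_tbl
#' @export
autoplot.cluster_profile_tbl <- function(object, ...) {
  summ <- object |>
    dplyr::group_by(.data$hemisphere, .data$cluster, .data$target) |>
    dplyr::summarise(
      mean = mean(.data$probability),
      se = sd(.data$probability) / sqrt(dplyr::n()),
      .groups = "drop"
    )
  ggplot2::ggplot(summ, ggplot2::aes(x = .data$target, y = .data$mean,
                                     fill = factor(.data$cluster))) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8),
                      width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$se,
                   ymax = .data$mean + .data$se),
      position = ggplot2::position_dodge(width = 0.8), width = 0.25
    ) +
    ggplot2::facet_wrap(~hemisphere) +
    ggplot2::labs(x = "target region", y = "connection probability",
                  fill = "cluster") +
    ggplot2::theme_minimal()
}

#' Axial-slice view of a consensus parcellation
#'
#' Tile map of the final consensus labels on one axial slice.
#'
#' @param object A `consensus_map` from [build_consensus()].
#' @param slice 1-based axial (k) slice index; defaults to the slice with
#'   the most labeled voxels.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot consensus_map
#' @export
autoplot.consensus_map <- function(object, slice = NULL, ...) {
  lab <- object$final_labels
  if (is.null(slice)) {
    slice <- which.max(apply(lab > 0, 3L, sum))
  }
  sl <- lab[, , slice]
  df <- tidyr::expand_grid(i = seq_len(nrow(sl)), j = seq_len(ncol(sl)))
  df$label <- sl[cbind(df$i, df$j)]
  df <- dplyr::filter(df, .data$label > 0)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$i, y = .data$j,
                                   fill = factor(.data$label))) +
    ggplot2::geom_tile() +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("consensus labels, axial slice %d", slice),
                  x = "i (voxel)", y = "j (voxel)", fill = "cluster") +
    ggplot2::theme_minimal()
}
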