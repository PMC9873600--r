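# End-to-end pipeline driver: phantom (or ingested) cohort -> connectivity
# -> per-subject parcellation -> harmonization -> consensus -> per-cluster
# probability ANOVA -> group tract-map algebra, with on-disk outputs and a
# reproducibility manifest.

#' Pipeline configuration
#'
#' Bundles the analysis parameters with the phantom configuration. The
#' defaults mirror a standard connectivity-based parcellation setup:
#' k = 3 clusters, consensus threshold 50%, proj_thresh sample threshold
#' 1250 (a quarter of the 5000 samples per voxel), tract-map threshold
#' 0.95, alpha 0.05 after Bonferroni correction.
#'
#' @param phantom A [phantom_config()] describing the synthetic cohort.
#' @param k Number of clusters.
#' @param consensus_threshold Fraction of subjects required for consensus.
#' @param proj_threshold Minimum total samples for proj_thresh.
#' @param tract_q Normalized tract-map threshold.
#' @param min_subjects Group tract-map subject-count threshold (defaults
#'   to the consensus count, `ceiling(consensus_threshold * n_subjects)`).
#' @param rng_seed Seed for the analysis stages (k-means restarts).
#' @param restarts k-means restarts per subject.
#' @param alpha Significance level for the corrected post-hoc tests.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(phantom = phantom_config(),
                            k = 3L,
                            consensus_threshold = 0.5,
                            proj_threshold = 1250,
                            tract_q = 0.95,
                            min_subjects = NULL,
                            rng_seed = phantom$rng_seed,
                            restarts = 20L,
                            alpha = 0.05) {
  stopifnot(inherits(phantom, "phantom_config"), k >= 1L,
            consensus_threshold > 0, consensus_threshold <= 1,
            proj_threshold >= 0, tract_q >= 0, tract_q <= 1,
            restarts >= 1L, alpha > 0, alpha < 1)
  structure(
    list(phantom = phantom, k = as.integer(k),
         consensus_threshold = consensus_threshold,
         proj_threshold = proj_threshold, tract_q = tract_q,
         min_subjects = min_subjects,
         rng_seed = as.integer(rng_seed), restarts = as.integer(restarts),
         alpha = alpha),
    class = "pipeline_config"
  )
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML file path.
#' @return `read_pipeline_config()` returns a `pipeline_config`;
#'   `write_pipeline_config()` returns `path` invisibly.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  ph <- y$phantom %||% list()
  if (!is.null(ph$cluster_profiles)) {
    ph$cluster_profiles <- do.call(rbind, ph$cluster_profiles)
  }
  phantom <- do.call(phantom_config, ph)
  args <- y[setdiff(names(y), "phantom")]
  do.call(pipeline_config, c(list(phantom = phantom), args))
}

#' @rdname read_pipeline_config
#' @param config A `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  ph <- config$phantom
  y <- list(
    phantom = list(
      grid_shape = ph$grid_shape, voxel_size = ph$voxel_size,
      n_targets = ph$n_targets, n_clusters = ph$n_clusters,
      samples_per_voxel = ph$samples_per_voxel,
      cluster_profiles = lapply(seq_len(nrow(ph$cluster_profiles)),
                                function(i) ph$cluster_profiles[i, ]),
      profile_noise = ph$profile_noise, jitter_sd = ph$jitter_sd,
      n_subjects = ph$n_subjects, rng_seed = ph$rng_seed
    ),
    k = config$k, consensus_threshold = config$consensus_threshold,
    proj_threshold = config$proj_threshold, tract_q = config$tract_q,
    min_subjects = config$min_subjects, rng_seed = config$rng_seed,
    restarts = config$restarts, alpha = config$alpha
  )
  yaml::write_yaml(y, path)
  invisible(path)
}

#' Run the full parcellation pipeline
#'
#' Generates (or takes) a cohort, builds per-subject connectivity and
#' cross-correlation matrices, parcellates each subject with k-means,
#' harmonizes labels across subjects, derives the thresholded consensus
#' map, quantifies per-cluster connection probabilities with one-way
#' ANOVA + Bonferroni post-hocs, and reduces per-cluster visitation maps
#' with the group tract-map algebra. All randomness derives from the
#' configured seeds, so a fixed configuration reproduces its outputs
#' bit-identically.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory; when given, NIfTI volumes,
#'   TSV tables and a JSON manifest are written there.
#' @param cohort Optional pre-generated [generate_cohort()] result
#'   (otherwise generated from `config$phantom`).
#' @return A `pipeline_result` list: `cohort`, `parcellations`
#'   (harmonized), `consensus`, `prob_maps`, `profile_table`,
#'   `anova` (tibble from [anova_all_targets()]), `tract_maps`,
#'   `summary` (tibble of headline cohort statistics).
#' @export
run_pipeline <- function(config, out_dir = NULL, cohort = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- "phantom"
  result <- tryCatch({
    cohort <- cohort %||% generate_cohort(config$phantom)
    gs <- dim(cohort$truth$labels)
    subjects <- drop_incomplete_subjects(cohort$subjects,
                                         n_targets = config$phantom$n_targets)
    if (nrow(subjects$dropped) > 0L) {
      message("run_pipeline: dropped ", nrow(subjects$dropped),
              " subject(s) with incomplete data")
    }
    subs <- subjects$kept

    stage <- "connectivity"
    cms <- lapply(subs, function(s) {
      build_connectivity_matrix(s$count_volumes, s$seed_mask,
                                subject_id = s$subject_id)
    })
    ccms <- lapply(cms, build_ccm)
    prob_maps <- lapply(subs, function(s) {
      proj_thresh(s$count_volumes, s$seed_mask,
                  threshold = config$proj_threshold,
                  subject_id = s$subject_id)
    })

    stage <- "parcellation"
    parcs <- lapply(seq_along(ccms), function(i) {
      kmeans_parcellate(ccms[[i]], k = config$k,
                        seed = subject_seed(config$rng_seed, i),
                        restarts = config$restarts)
    })
    parcs <- harmonize_labels(parcs, cms, reference = "fingerprint")

    stage <- "consensus"
    consensus <- build_consensus(parcs, gs,
                                 threshold_fraction =
                                   config$consensus_threshold)

    stage <- "groupstats"
    profile_table <- build_profile_table(prob_maps,
                                         consensus$final_labels)
    anova_tbl <- anova_all_targets(profile_table, alpha = config$alpha)

    stage <- "tractmaps"
    min_subj <- config$min_subjects %||%
      ceiling(config$consensus_threshold * length(subs))
    tract_maps <- lapply(seq_len(config$k), function(c_) {
      # per-subject visitation stand-in: total streamline counts over the
      # subject's voxels carrying harmonized label c
      maps <- lapply(seq_along(subs), function(i) {
        total <- Reduce(`+`, subs[[i]]$count_volumes)
        lab <- parcellation_volume(parcs[[i]], gs)
        out <- total * (lab == c_)
        as_volume(array(as.numeric(out), dim = gs), subs[[i]]$affine)
      })
      group_tract_map(maps, q = config$tract_q, min_subjects = min_subj)
    })

    stage <- "summary"
    truth_labels <- cohort$truth$labels
    seed_idx <- which(truth_labels > 0L)
    ari <- adjusted_rand_index(truth_labels[seed_idx],
                               consensus$final_labels[seed_idx])
    flags <- vapply(parcs, function(p) {
      classify_pattern(p, grid_shape = gs)$pattern
    }, logical(1))
    vols <- cluster_volumes(consensus$final_labels)
    summary_tbl <- tibble::tibble(
      statistic = c("n_subjects", "n_seed_voxels", "consensus_ari",
                    "pattern_fraction",
                    paste0("volume_mm3_cluster", vols$cluster)),
      value = c(length(subs), length(seed_idx), ari, mean(flags),
                vols$volume_mm3)
    )
    list(cohort = cohort, connectivity = cms, ccms = ccms,
         prob_maps = prob_maps, parcellations = parcs,
         consensus = consensus, profile_table = profile_table,
         anova = anova_tbl, tract_maps = tract_maps,
         summary = summary_tbl, config = config)
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  if (!is.null(out_dir)) {
    write_pipeline_outputs(result, out_dir)
  }
  structure(result, class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  print(x$summary, n = Inf)
  invisible(x)
}

# Write NIfTI volumes, TSV tables and the JSON manifest for a pipeline run.
write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  gs <- dim(result$cohort$truth$labels)
  write_volume(result$cohort$truth$labels,
               file.path(out_dir, "truth_labels.nii.gz"))
  write_volume(result$consensus$final_labels,
               file.path(out_dir, "consensus_labels.nii.gz"))
  for (c_ in seq_len(result$consensus$k)) {
    write_volume(result$consensus$counts[[c_]],
                 file.path(out_dir, sprintf("consensus_count_cluster%d.nii.gz",
                                            c_)))
  }
  utils::write.table(result$profile_table,
                     file.path(out_dir, "profile_table.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(dplyr::select(result$anova, -"fit"),
                     file.path(out_dir, "anova.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(result$summary, file.path(out_dir, "summary.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  cfg_path <- file.path(out_dir, "config.yaml")
  write_pipeline_config(result$config, cfg_path)
  manifest <- list(
    package = "cbparcel",
    version = as.character(utils::packageVersion("cbparcel")),
    rng_seed = result$config$rng_seed,
    phantom_seed = result$config$phantom$rng_seed,
    parameters = list(
      k = result$config$k,
      consensus_threshold = result$config$consensus_threshold,
      proj_threshold = result$config$proj_threshold,
      tract_q = result$config$tract_q,
      alpha = result$config$alpha,
      restarts = result$config$restarts
    ),
    grid_shape = gs,
    n_subjects = length(result$cohort$subjects),
    config = "config.yaml"
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}

#' Write a cohort to disk as NIfTI volumes plus a JSON manifest
#'
#' One directory per subject containing per-target count volumes
#' (`counts_<target>.nii.gz`), the seed mask and the true labels; the
#' ground truth and a cohort manifest at the top level.
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_volume(cohort$truth$labels, file.path(dir, "truth_labels.nii.gz"))
  write_volume(cohort$truth$seed_mask + 0L,
               file.path(dir, "truth_seed_mask.nii.gz"),
               affine = cohort$truth$affine)
  for (s in cohort$subjects) {
    sdir <- file.path(dir, s$subject_id)
    dir.create(sdir, showWarnings = FALSE)
    for (t_ in names(s$count_volumes)) {
      write_volume(s$count_volumes[[t_]],
                   file.path(sdir, sprintf("counts_%s.nii.gz", t_)))
    }
    write_volume(s$seed_mask + 0L, file.path(sdir, "seed_mask.nii.gz"),
                 affine = s$affine)
    write_volume(s$true_labels, file.path(sdir, "true_labels.nii.gz"))
  }
  manifest <- list(
    n_subjects = length(cohort$subjects),
    subject_ids = vapply(cohort$subjects, `[[`, character(1), "subject_id"),
    targets = names(cohort$subjects[[1L]]$count_volumes),
    rng_seed = cohort$config$rng_seed
  )
  jsonlite::write_json(manifest, file.path(dir, "cohort.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Read a cohort previously written with [write_cohort()]
#'
#' @param dir Cohort directory.
#' @return A `phantom_cohort`-shaped list (without the generator config).
#' @export
read_cohort <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "cohort.json"),
                                  simplifyVector = TRUE)
  truth_labels <- read_volume(file.path(dir, "truth_labels.nii.gz"))
  truth_labels <- as_volume(array(as.integer(round(truth_labels)),
                                  dim = dim(truth_labels)),
                            attr(truth_labels, "affine"))
  subjects <- lapply(manifest$subject_ids, function(sid) {
    sdir <- file.path(dir, sid)
    cvs <- lapply(manifest$targets, function(t_) {
      read_volume(file.path(sdir, sprintf("counts_%s.nii.gz", t_)))
    })
    names(cvs) <- manifest$targets
    seed <- read_volume(file.path(sdir, "seed_mask.nii.gz"))
    lab <- read_volume(file.path(sdir, "true_labels.nii.gz"))
    structure(
      list(subject_id = sid, count_volumes = cvs,
           seed_mask = as_volume(seed != 0, attr(seed, "affine")),
           true_labels = as_volume(array(as.integer(round(lab)),
                                         dim = dim(lab)),
                                   attr(lab, "affine")),
           affine = attr(seed, "affine")),
      class = "phantom_subject"
    )
  })
  structure(
    list(truth = list(labels = truth_labels,
                      seed_mask = truth_labels > 0L,
                      affine = attr(truth_labels, "affine")),
         subjects = subjects),
    class = "phantom_cohort"
  )
}
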