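#' Run configuration for the full analysis
#'
#' Collects every stage parameter and per-stage seed in one round-trippable
#' list. Two preprocessing branches are maintained: the association branch
#' works on unsmoothed series and smooths the z-scored association map,
#' while the seed-FC branch smooths the BOLD volumes before the temporal
#' steps.
#'
#' @param workdir Run directory.
#' @param cohort A [cohort_config()] (the synthetic input; omit `NULL` when
#'   analysing data already on disk).
#' @param n_drop,fd_threshold,scrub_window,band,global_signal,filter_type
#'   Preprocessing parameters (see [preprocess_subject()]).
#' @param r_threshold Correlation threshold for the voxel graph.
#' @param fwhm_mm Gaussian smoothing FWHM in mm.
#' @param voxel_p,cluster_p,n_perm,connectivity Group-inference parameters.
#' @param svm_cost Linear-SVM cost.
#' @param seed_simulate,seed_permutation Stage seeds (required).
#' @return List of class `run_config`.
#' @export
run_config <- function(workdir = "assomap_run",
                       cohort = cohort_config(),
                       n_drop = 10, fd_threshold = 0.5,
                       scrub_window = c(2, 1), band = c(0.01, 0.1),
                       global_signal = TRUE, filter_type = "butterworth",
                       r_threshold = 0.25, fwhm_mm = 6,
                       voxel_p = 0.001, cluster_p = 0.05, n_perm = 1000,
                       connectivity = 18, svm_cost = 1,
                       seed_simulate = 1L, seed_permutation = 7L) {
  cfg <- as.list(environment())
  for (s in c("seed_simulate", "seed_permutation"))
    if (is.null(cfg[[s]]) || !is.finite(cfg[[s]]))
      stop("missing seed: ", s, call. = FALSE)
  structure(cfg, class = "run_config")
}

#' Write / read a run configuration as YAML
#'
#' @param config A [run_config()].
#' @param path YAML path.
#' @return The path (write) or the reconstructed `run_config` (read).
#' @export
write_run_config <- function(config, path) {
  plain <- unclass(config)
  plain$cohort <- if (!is.null(config$cohort)) unclass(config$cohort)
  yaml::write_yaml(plain, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  plain <- yaml::read_yaml(path)
  cohort <- if (!is.null(plain$cohort)) {
    cc <- plain$cohort
    cc$grid <- as.numeric(cc$grid)
    cc$dmn_regions <- as.numeric(cc$dmn_regions)
    do.call(cohort_config, cc)
  }
  plain$cohort <- NULL
  cfg <- do.call(run_config, c(plain, list(cohort = cohort)))
  cfg
}

#' Per-subject association-branch maps for a whole cohort
#'
#' Preprocesses each subject (no spatial smoothing of the series), builds
#' the thresholded voxel graph, and returns the smoothed z-scored
#' association map (and optionally the degree-centrality map) per subject.
#'
#' @param cohort A `synthetic_cohort` (or any list with the same shape).
#' @param r_threshold Correlation threshold.
#' @param fwhm_mm Smoothing FWHM applied to the z maps.
#' @param with_fcs Also return degree-centrality z maps.
#' @param ... Passed to [preprocess_subject()].
#' @return List with `asso_z` (list of [voxel_map()]), optionally `fcs_z`,
#'   and `info` (per-subject flagged-frame counts and exclusion flags).
#' @export
cohort_asso_maps <- function(cohort, r_threshold = 0.25, fwhm_mm = 6,
                             with_fcs = FALSE, ...) {
  masks <- cohort$masks
  asso_z <- list(); fcs_z <- list(); info <- list()
  for (i in seq_along(cohort$subjects)) {
    s <- cohort$subjects[[i]]
    pp <- preprocess_subject(s$bold, s$motion, masks, ...)
    graph <- voxel_graph(pp$bold, masks$brain, r_threshold)
    am <- compute_asso_map(pp$bold, masks$brain, graph = graph)
    asso_z[[i]] <- smooth_map(zscore_map(am$map), fwhm_mm)
    if (with_fcs)
      fcs_z[[i]] <- smooth_map(
        zscore_map(compute_fcs_map(pp$bold, masks$brain, graph = graph)),
        fwhm_mm)
    info[[i]] <- data.frame(subject_id = s$bold$subject_id,
                            n_flagged = pp$n_flagged,
                            excluded = pp$excluded)
  }
  out <- list(asso_z = asso_z, info = do.call(rbind, info))
  if (with_fcs) out$fcs_z <- fcs_z
  out
}

#' Per-subject seed-FC maps for a whole cohort
#'
#' The seed-FC branch re-preprocesses from the raw series with spatial
#' smoothing *before* the temporal steps, then correlates every in-mask
#' voxel with the mean seed series (Fisher z).
#'
#' @param cohort A `synthetic_cohort`.
#' @param seed_mask Logical 3-D seed mask (e.g. a suprathreshold cluster
#'   from the association contrast).
#' @param fwhm_mm FWHM for the pre-smoothing of the BOLD series.
#' @param preprocessed Optional list of already-preprocessed FC-branch
#'   [bold_dataset()]s (from [cohort_fc_preprocess()]), reused across seed
#'   masks.
#' @param ... Passed to [preprocess_subject()].
#' @return List of per-subject [voxel_map()]s of kind `"fc_z"`.
#' @export
cohort_fc_maps <- function(cohort, seed_mask, fwhm_mm = 6,
                           preprocessed = NULL, ...) {
  if (is.null(preprocessed))
    preprocessed <- cohort_fc_preprocess(cohort, fwhm_mm, ...)
  lapply(preprocessed, compute_seed_fc_map, seed = seed_mask,
         mask = cohort$masks$brain)
}

#' @rdname cohort_fc_maps
#' @export
cohort_fc_preprocess <- function(cohort, fwhm_mm = 6, ...) {
  masks <- cohort$masks
  lapply(cohort$subjects, function(s)
    preprocess_subject(s$bold, s$motion, masks,
                       smooth_fwhm_mm = fwhm_mm, ...)$bold)
}

#' Full in-memory analysis of a cohort
#'
#' Association branch, permutation cluster inference, seed definition from
#' the largest significant association cluster, seed-FC branch and its
#' inference, cluster-mean features, leave-one-out SVM, and brain-behavior
#' correlations.
#'
#' @param cohort A `synthetic_cohort`.
#' @param config A [run_config()] supplying all stage parameters.
#' @return List of class `assomap_analysis` with elements `asso`
#'   (a `cluster_correction`), `seed_label`, `fc` (a `cluster_correction`
#'   or `NULL`), `features`, `classifier`, `correlations`, `subject_info`.
#' @export
analyze_cohort <- function(cohort, config = run_config()) {
  pp_args <- list(n_drop = config$n_drop, band = config$band,
                  fd_threshold = config$fd_threshold,
                  scrub_window = config$scrub_window,
                  global_signal = config$global_signal,
                  filter_type = config$filter_type)
  branch <- do.call(cohort_asso_maps,
                    c(list(cohort, r_threshold = config$r_threshold,
                           fwhm_mm = config$fwhm_mm), pp_args))
  design <- make_design(cohort$phenotypes)
  asso_res <- permutation_cluster_correction(
    branch$asso_z, design, n_perm = config$n_perm,
    voxel_p = config$voxel_p, cluster_p = config$cluster_p,
    connectivity = config$connectivity, seed = config$seed_permutation)

  cl <- asso_res$clusters
  sig <- cl[cl$significant, , drop = FALSE]
  fc_res <- NULL; seed_label <- NULL
  features <- NULL; classifier <- NULL; correlations <- NULL
  if (nrow(sig)) {
    pick <- sig$cluster_id[which.max(sig$extent)]
    labarr <- attr(cl, "labels")
    seed_mask <- abs(labarr) == pick
    seed_label <- sprintf("assoC%d", pick)
    fcz <- do.call(cohort_fc_maps,
                   c(list(cohort, seed_mask, fwhm_mm = config$fwhm_mm),
                     pp_args))
    fc_res <- permutation_cluster_correction(
      fcz, design, n_perm = config$n_perm, voxel_p = config$voxel_p,
      cluster_p = config$cluster_p, connectivity = config$connectivity,
      seed = config$seed_permutation + 1L)

    fmaps <- list(); fmasks <- list()
    fmaps[[paste0("asso_z:", seed_label)]] <- branch$asso_z
    fmasks[[paste0("asso_z:", seed_label)]] <- seed_mask
    fcl <- fc_res$clusters
    fsig <- fcl[fcl$significant, , drop = FALSE]
    if (nrow(fsig)) {
      flab <- attr(fcl, "labels")
      for (cid in fsig$cluster_id) {
        nm <- sprintf("fcz:%s->fcC%d", seed_label, cid)
        fmaps[[nm]] <- fcz
        fmasks[[nm]] <- abs(flab) == cid
      }
    }
    features <- extract_cluster_features(fmaps, fmasks)
    classifier <- loocv_linear_svm(features, cohort$phenotypes$group,
                                   cost = config$svm_cost)
    correlations <- pearson_with_fdr(
      features, cohort$phenotypes[, c("mmse", "moca")])
  }
  structure(list(asso = asso_res, seed_label = seed_label, fc = fc_res,
                 features = features, classifier = classifier,
                 correlations = correlations,
                 subject_info = branch$info),
            class = "assomap_analysis")
}

write_manifest <- function(dir, stage, params, outputs) {
  man <- list(stage = stage, params = params,
              outputs = as.list(tools::md5sum(sort(outputs))))
  jsonlite::write_json(man, file.path(dir, paste0(stage, "_manifest.json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Run the whole study from one configuration, writing a run directory
#'
#' Stages: simulate, association branch + inference, seed-FC branch +
#' inference, features, classifier, correlations. Each stage writes its
#' outputs plus a JSON manifest of parameters and output checksums, so a
#' rerun with an identical configuration reproduces identical manifests.
#'
#' @param config A [run_config()] with a non-`NULL` `cohort`.
#' @return The run directory path, invisibly; side effects on disk:
#'   `cohort/`, `maps/`, `stats/clusters.tsv`, `stats/t.nii.gz`,
#'   `features.tsv`, `report.json`, `corr.tsv` and per-stage manifests.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(config$cohort)) stop("run_all needs a cohort config",
                                   call. = FALSE)
  wd <- config$workdir
  dir.create(wd, recursive = TRUE, showWarnings = FALSE)
  write_run_config(config, file.path(wd, "config.yaml"))

  ccfg <- config$cohort
  ccfg$seed <- config$seed_simulate
  cohort <- simulate_cohort(ccfg)
  cdir <- file.path(wd, "cohort")
  write_cohort(cohort, cdir)
  write_manifest(wd, "simulate", list(seed = config$seed_simulate),
                 list.files(cdir, full.names = TRUE))

  res <- analyze_cohort(cohort, config)

  sdir <- file.path(wd, "stats")
  dir.create(sdir, showWarnings = FALSE)
  write_nifti_volume(res$asso$stat$map, file.path(sdir, "asso_t.nii.gz"))
  ctab <- res$asso$clusters
  utils::write.table(ctab, file.path(sdir, "asso_clusters.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(data.frame(max_extent = res$asso$null_max_extent),
                     file.path(sdir, "asso_perm_null.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  outs <- file.path(sdir, c("asso_t.nii.gz", "asso_clusters.tsv",
                            "asso_perm_null.tsv"))
  if (!is.null(res$fc)) {
    write_nifti_volume(res$fc$stat$map, file.path(sdir, "fc_t.nii.gz"))
    utils::write.table(res$fc$clusters, file.path(sdir, "fc_clusters.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    outs <- c(outs, file.path(sdir, c("fc_t.nii.gz", "fc_clusters.tsv")))
  }
  write_manifest(wd, "stats",
                 config[c("r_threshold", "fwhm_mm", "voxel_p", "cluster_p",
                          "n_perm", "connectivity", "seed_permutation")],
                 outs)

  outs <- character()
  if (!is.null(res$features)) {
    ftab <- data.frame(subject_id = cohort$phenotypes$subject_id,
                       group = cohort$phenotypes$group,
                       res$features, check.names = FALSE)
    utils::write.table(ftab, file.path(wd, "features.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    rep <- res$classifier
    jsonlite::write_json(
      list(accuracy = rep$accuracy, sensitivity = rep$sensitivity,
           specificity = rep$specificity, auc = rep$auc,
           confusion = as.list(rep$confusion),
           predictions = rep$predictions,
           decision_values = rep$decision_values),
      file.path(wd, "report.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
    utils::write.table(res$correlations, file.path(wd, "corr.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    outs <- file.path(wd, c("features.tsv", "report.json", "corr.tsv"))
    write_manifest(wd, "report", list(svm_cost = config$svm_cost), outs)
  }
  invisible(wd)
}
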