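# Per-patient orchestration and cohort batching.
#
# analyze_patient runs attenuation -> heterogeneity -> centralization on one
# CT + segmentation pair and returns the six headline metrics (3 proportions,
# 2 entropies, 1 slope) with QC flags and full provenance (config hash, seed,
# package version). Stages after classification are independent: a failure in
# a late stage is recorded without discarding earlier metrics.

#' Run configuration
#'
#' Every analysis parameter in one serializable object, embedded (with its
#' hash) in every report so a run can be reproduced from its output.
#'
#' @param clip_range HU window for lung samples.
#' @param bins spatial-histogram bins per axis (heterogeneity).
#' @param n_regions radial shells (centralization).
#' @param vb a [vb_config()] for the attenuation mixture.
#' @param seed integer seed for all randomized steps.
#' @param label_map multi-label segmentation labels.
#' @param min_lung_voxels minimum voxel count per lung.
#' @param include_oligemic also report oligemic entropy (off the headline).
#' @return A list of class `run_config`.
#' @export
run_config <- function(clip_range = c(-1024, 100), bins = 32L,
                       n_regions = 21L, vb = vb_config(), seed = 1L,
                       label_map = list(lung_left = 1L, lung_right = 2L,
                                        veins = 3L),
                       min_lung_voxels = 1000,
                       include_oligemic = FALSE) {
  structure(list(clip_range = clip_range, bins = as.integer(bins),
                 n_regions = as.integer(n_regions), vb = unclass(vb),
                 seed = as.integer(seed), label_map = label_map,
                 min_lung_voxels = min_lung_voxels,
                 include_oligemic = include_oligemic),
            class = "run_config")
}

#' @rdname run_config
#' @param config a [run_config()].
#' @export
config_hash <- function(config) {
  fnv1a32(as.character(jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                                        digits = NA)))
}

#' Analyze one patient
#'
#' @param ct a [ct_volume()] or a NIfTI path.
#' @param seg a [segmentation_set()], a multi-label NIfTI path, or a named
#'   list of per-structure paths (see [read_segmentation()]).
#' @param config a [run_config()].
#' @param patient_id identifier copied into the report.
#' @param out_json optional path; when given, the metrics are written as JSON.
#' @param export_dir optional directory for NIfTI exports of the compartment
#'   mask (`compartments.nii.gz`) and per-lung centralization maps.
#' @return A `patient_metrics` list: `patient_id`, the six headline metrics
#'   (`prop_oligemic`, `prop_normal`, `prop_hyperemic`, `entropy_high`,
#'   `entropy_medium`, `slope_mean`) plus per-lung/secondary fields, `model`,
#'   `qc` flags, `errors` (named by failed stage), and provenance.
#' @export
analyze_patient <- function(ct, seg, config = run_config(),
                            patient_id = "patient", out_json = NULL,
                            export_dir = NULL) {
  if (is.character(ct)) ct <- read_ct_volume(ct)
  if (!inherits(seg, "segmentation_set"))
    seg <- read_segmentation(seg, ct, label_map = config$label_map,
                             min_lung_voxels = config$min_lung_voxels)
  qc <- ct$qc
  errors <- list()
  res <- list(patient_id = patient_id)

  # attenuation: pooled both-lung fit, then voxel classification
  smpL <- extract_lung_samples(ct, seg, "left", config$clip_range)
  smpR <- extract_lung_samples(ct, seg, "right", config$clip_range)
  qc <- c(qc, smpL$qc, smpR$qc)
  model <- fit_attenuation_model(c(smpL$values, smpR$values),
                                 config = do.call(vb_config, config$vb),
                                 seed = config$seed)
  if (!model$fit_info$converged) qc <- c(qc, "mixture fit did not converge")
  cmask <- classify_voxels(ct, seg, model, config$clip_range)
  props <- compartment_proportions(model, cmask)
  res$prop_oligemic <- props$weight_based[1]
  res$prop_normal <- props$weight_based[2]
  res$prop_hyperemic <- props$weight_based[3]
  res$prop_count_based <- setNames(props$count_based, props$compartment)
  res$model <- model

  # heterogeneity
  het <- tryCatch(
    heterogeneity_metrics(cmask, seg, bins = config$bins,
                          include_oligemic = config$include_oligemic),
    error = function(e) e)
  if (inherits(het, "error")) {
    errors$heterogeneity <- conditionMessage(het)
  } else {
    res$entropy_high <- het$entropy_high_mean
    res$entropy_medium <- het$entropy_medium_mean
    res$entropy_per_lung <- het[grep("^entropy_", names(het))]
    qc <- c(qc, het$flags)
  }

  # centralization
  cen <- tryCatch(
    centralization_metric(ct, seg, config$clip_range, config$n_regions),
    error = function(e) e)
  if (inherits(cen, "error")) {
    errors$centralization <- conditionMessage(cen)
  } else {
    res$slope_mean <- cen$slope_mean
    res$slope_left <- cen$slope_left
    res$slope_right <- cen$slope_right
    res$r2_left <- cen$r2_left
    res$r2_right <- cen$r2_right
    res$profiles <- cen$profiles
  }

  res$qc <- qc
  res$errors <- errors
  res$config <- unclass(config)
  res$config_hash <- config_hash(config)
  res$seed <- config$seed
  res$version <- as.character(packageVersion("perfmosaic"))
  class(res) <- "patient_metrics"

  if (!is.null(export_dir)) {
    dir.create(export_dir, showWarnings = FALSE, recursive = TRUE)
    write_ct_volume(unclass(cmask), file.path(export_dir, "compartments.nii.gz"),
                    spacing = ct$spacing, datatype = "uint8")
  }
  if (!is.null(out_json)) write_patient_json(res, out_json)
  res
}

#' Serialize patient metrics to JSON
#'
#' @param metrics a `patient_metrics` from [analyze_patient()].
#' @param path output path.
#' @param timestamp include a generation timestamp (on by default; turn off
#'   for byte-identical reproduction checks).
#' @return `path`, invisibly.
#' @export
write_patient_json <- function(metrics, path, timestamp = TRUE) {
  x <- unclass(metrics)
  x$model <- list(components = x$model$components,
                  fit_info = x$model$fit_info[c("n_samples_used",
                                                "n_iterations", "converged")])
  x$profiles <- lapply(x$profiles, function(p) as.data.frame(unclass(p)))
  if (timestamp) x$timestamp <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)
  invisible(path)
}

#' Extract the headline-metric row of one patient
#'
#' @param metrics a `patient_metrics`.
#' @return One-row data frame with the six headline metrics and provenance.
#' @export
metrics_row <- function(metrics) {
  g <- function(f) if (is.null(metrics[[f]])) NA_real_ else metrics[[f]]
  data.frame(patient_id = metrics$patient_id,
             prop_oligemic = g("prop_oligemic"),
             prop_normal = g("prop_normal"),
             prop_hyperemic = g("prop_hyperemic"),
             entropy_high = g("entropy_high"),
             entropy_medium = g("entropy_medium"),
             slope_mean = g("slope_mean"),
             n_qc_flags = length(metrics$qc),
             n_errors = length(metrics$errors),
             config_hash = metrics$config_hash,
             seed = metrics$seed,
             version = metrics$version)
}

#' Analyze a cohort from a manifest
#'
#' @param manifest data frame (or CSV path) with columns `patient_id`,
#'   `ct_path`, `seg_path`. Per-patient failures are recorded in the output
#'   without aborting the batch.
#' @param config a [run_config()].
#' @param out_csv optional path for the metrics table.
#' @return Data frame with one row per manifest entry; failed patients carry
#'   `NA` metrics and the error message in `failure`.
#' @export
analyze_cohort <- function(manifest, config = run_config(), out_csv = NULL) {
  if (is.character(manifest)) {
    if (!file.exists(manifest)) stopf("manifest not found: %s", manifest)
    manifest <- read.csv(manifest, stringsAsFactors = FALSE)
  }
  need <- c("patient_id", "ct_path", "seg_path")
  if (!all(need %in% names(manifest)))
    stopf("manifest must have columns: %s", paste(need, collapse = ", "))
  rows <- lapply(seq_len(nrow(manifest)), function(i) {
    pm <- tryCatch(
      analyze_patient(manifest$ct_path[i], manifest$seg_path[i], config,
                      patient_id = manifest$patient_id[i]),
      error = function(e) e)
    if (inherits(pm, "error")) {
      row <- metrics_row(list(patient_id = manifest$patient_id[i],
                              qc = character(0), errors = list(),
                              config_hash = config_hash(config),
                              seed = config$seed,
                              version = as.character(
                                packageVersion("perfmosaic"))))
      row$failure <- conditionMessage(pm)
      row
    } else {
      row <- metrics_row(pm)
      row$failure <- NA_character_
      row
    }
  })
  out <- do.call(rbind, rows)
  if (!is.null(out_csv)) write.csv(out, out_csv, row.names = FALSE)
  out
}
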