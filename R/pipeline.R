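# End-to-end pipeline on a synthetic cohort: simulate, quantify, analyze,
# write tables/maps/log. Everything is a pure function of the config
# (including its seed), so reruns are bit-identical.

#' Build a pipeline configuration
#'
#' Assembles (and validates) the configuration for [run_full_pipeline()].
#' Defaults reproduce the desk-scale study conditions: a 2 x 2 cohort of
#' n = 6 per sex per genotype, one section per animal, one WT male excluded
#' from the morphometry arm, FDR 1% on voxel maps, ANOVA at alpha 0.05.
#'
#' @param out_dir Output directory (created if absent).
#' @param seed Master seed for every stochastic stage.
#' @param n_per_cell Animals per sex x genotype cell.
#' @param mri_exclude Subject ids excluded from the morphometry arm only.
#' @param antibody Stain simulated/quantified in the IHC arm.
#' @param ihc List of overrides for [ihc_sim_params()].
#' @param ihc_effects Named planted effects on the signal fraction
#'   (`sex`, `genotype`, `interaction`).
#' @param roi_grid ROI parcellation of synthetic sections, `c(nr, nc)`.
#' @param morph List of overrides for [morphometry_sim_params()].
#' @param fdr_level Voxel-map FDR level.
#' @param alpha ANOVA significance level.
#' @param min_object_area Object-count size filter, pixels.
#' @return A list of class `run_config`.
#' @export
pipeline_config <- function(out_dir, seed = 1L, n_per_cell = 6,
                            mri_exclude = "M_WT_1", antibody = "GFAP",
                            ihc = list(), ihc_effects = c(genotype = -0.03),
                            roi_grid = c(2, 2), morph = list(),
                            fdr_level = 0.01, alpha = 0.05,
                            min_object_area = DEFAULT_MIN_OBJECT_AREA) {
  cfg <- list(out_dir = out_dir, seed = as.integer(seed),
              n_per_cell = n_per_cell, mri_exclude = mri_exclude,
              antibody = antibody, ihc = ihc, ihc_effects = ihc_effects,
              roi_grid = roi_grid, morph = morph, fdr_level = fdr_level,
              alpha = alpha, min_object_area = min_object_area)
  if (fdr_level <= 0 || fdr_level > 1) stop("`fdr_level` must be in (0, 1]",
                                            call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must be in (0, 1)", call. = FALSE)
  class(cfg) <- "run_config"
  cfg
}

#' Load a pipeline configuration from JSON
#'
#' Validates that any referenced paths exist before any computation starts.
#'
#' @param path JSON file of [pipeline_config()] fields.
#' @return A `run_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("config file not found: %s", path), call. = FALSE)
  }
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  args <- raw[intersect(names(raw), names(formals(pipeline_config)))]
  cfg <- do.call(pipeline_config, args)
  for (field in c("design_path")) {
    if (!is.null(raw[[field]]) && !file.exists(raw[[field]])) {
      stop(sprintf("configured path does not exist: %s = %s", field,
                   raw[[field]]), call. = FALSE)
    }
  }
  cfg
}

write_csv_out <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

#' Run the full synthetic-cohort analysis pipeline
#'
#' Stages: (1) simulate the IHC cohort and quantify every section over a
#' tiled ROI parcellation; (2) per-region two-way sex x genotype ANOVA of the
#' percent-positive areas; (3) simulate the morphometry cohort (with the
#' configured exclusion) and run volume integration, per-sex voxel-wise
#' statistics with FDR control, and structure-level tests. All tables (CSV),
#' voxel maps (NIfTI) and a run log go to `config$out_dir`; the log and
#' `run_info.json` record the md5 hash of the written config so outputs are
#' traceable to their exact parameters.
#'
#' @param config A `run_config` from [pipeline_config()] or [read_config()].
#' @return Invisibly, a list with the in-memory results (`ihc`,
#'   `ihc_anova`, `morphometry`) and `files` written.
#' @export
run_full_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  log_lines <- character(0)
  log_add <- function(fmt, ...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                    sprintf(fmt, ...))
    log_lines <<- c(log_lines, line)
    message(line)
  }

  cfg_path <- file.path(out, "config.json")
  jsonlite::write_json(unclass(config), cfg_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  cfg_hash <- unname(tools::md5sum(cfg_path))
  log_add("config written (md5 %s)", cfg_hash)

  # --- IHC arm -------------------------------------------------------------
  design_ihc <- cohort_design(config$n_per_cell)
  ihc_params <- do.call(ihc_sim_params,
                        c(config$ihc, list(seed = config$seed)))
  cohort <- simulate_ihc_cohort(design_ihc, ihc_params,
                                effects = config$ihc_effects,
                                antibody = config$antibody)
  rois <- synthetic_roi_grid(ihc_params$image_shape,
                             config$roi_grid[1], config$roi_grid[2])
  measurements <- quantify_batch(cohort$sections, rois,
                                 min_object_area = config$min_object_area)
  log_add("IHC: %d sections quantified over %d ROIs",
          length(cohort$sections), length(rois$name_map))
  anova_tab <- batch_anova(measurements, "percent_positive_area",
                           group_by = "region", alpha = config$alpha)

  # --- morphometry arm -----------------------------------------------------
  design_mri <- cohort_design(config$n_per_cell, exclude = config$mri_exclude)
  morph_params <- do.call(morphometry_sim_params,
                          c(config$morph, list(seed = config$seed + 1L)))
  mcohort <- simulate_morphometry_cohort(design_mri, morph_params)
  morph <- run_morphometry(mcohort$atlas, mcohort$jacobians, design_mri,
                           level = config$fdr_level)
  n_brain <- sum(mcohort$atlas$labels > 0)
  log_add("morphometry: %d subjects, %d brain voxels tested per stratum",
          nrow(design_mri), n_brain)
  for (sx in names(morph$voxel_stats)) {
    log_add("stratum %s: %d undefined-variance voxels excluded, %d significant at q <= %g",
            sx, morph$voxel_stats[[sx]]$n_undefined,
            sum(morph$voxel_stats[[sx]]$significant, na.rm = TRUE),
            config$fdr_level)
  }

  # --- outputs -------------------------------------------------------------
  files <- c(
    write_csv_out(design_ihc, file.path(out, "design_ihc.csv")),
    write_csv_out(design_mri, file.path(out, "design_mri.csv")),
    write_csv_out(cohort$truth, file.path(out, "ihc_truth.csv")),
    write_csv_out(measurements, file.path(out, "ihc_measurements.csv")),
    write_csv_out(anova_tab, file.path(out, "ihc_anova.csv")),
    write_csv_out(morph$volumes, file.path(out, "volumes.csv")),
    write_csv_out(morph$structure_tests, file.path(out, "structure_tests.csv"))
  )
  write_atlas(mcohort$atlas, file.path(out, "atlas.nii.gz"),
              file.path(out, "atlas_names.json"))
  for (sx in names(morph$voxel_stats)) {
    vs <- morph$voxel_stats[[sx]]
    write_nifti_array(vs$t, file.path(out, sprintf("tmap_%s.nii.gz", sx)),
                      mcohort$atlas$voxel_size)
    qv <- vs$q; qv[is.na(qv)] <- 1
    write_nifti_array(qv, file.path(out, sprintf("qmap_%s.nii.gz", sx)),
                      mcohort$atlas$voxel_size)
    write_nifti_array(vs$significant + 0,
                      file.path(out, sprintf("sigmask_%s.nii.gz", sx)),
                      mcohort$atlas$voxel_size)
  }

  elapsed <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  log_add("pipeline finished in %.1f s", elapsed)
  info <- list(config_hash = cfg_hash, seed = config$seed,
               n_ihc_sections = length(cohort$sections),
               n_mri_subjects = nrow(design_mri),
               n_brain_voxels = n_brain,
               n_undefined = vapply(morph$voxel_stats,
                                    function(v) v$n_undefined, numeric(1)),
               elapsed_sec = elapsed,
               r_version = as.character(getRversion()))
  jsonlite::write_json(info, file.path(out, "run_info.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  writeLines(c(sprintf("config_hash: %s", cfg_hash), log_lines),
             file.path(out, "run_log.txt"))
  invisible(list(ihc = measurements, ihc_anova = anova_tab,
                 morphometry = morph, truth = list(ihc = cohort$truth,
                                                   morph = mcohort$truth),
                 files = files, config_hash = cfg_hash))
}
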