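#' Configure a pipeline run
#'
#' Collects every knob of the end-to-end pipeline in one validated record;
#' the config (with all seeds) is serialized verbatim into the run manifest
#' so outputs are reproducible bit-for-bit.
#'
#' @param mode `"table"` (cohort generation + statistics) or `"image"`
#'   (full 4D synthesis through mask recovery and index extraction).
#' @param seed master integer seed; stage seeds are derived from it
#'   deterministically.
#' @param cohort a [cohort_config()] (table mode).
#' @param n_subjects,loadings,n_volumes,tr_s,grid_shape,voxel_size_mm image-mode
#'   generation settings (`loadings` as in [generate_run()]).
#' @param nuisance_scale image-mode nuisance amplitude multiplier.
#' @param n_perm,alpha,tfce_e,tfce_h,connectivity permutation-inference
#'   settings.
#' @param group_smooth_fwhm_mm FWHM for group-level map smoothing; 0 disables
#'   smoothing (used for sharp-boundary synthetic recovery runs).
#' @param mask_source `"young"` or `"older-negative"`: which healthy
#'   subpopulation's maps would seed mask building (recorded in provenance;
#'   the synthetic generator has a single healthy population).
#' @param families,fd_adjust,both_networks statistics-suite settings.
#' @param output_dir run directory (created if needed).
#' @return Object of class `run_config`.
#' @export
run_config <- function(mode = c("table", "image"), seed = 1L,
                       cohort = cohort_config(),
                       n_subjects = 20L, loadings = c(at = 0.7, pm = 0.7),
                       n_volumes = 120L, tr_s = 2.382,
                       grid_shape = c(20L, 20L, 12L),
                       voxel_size_mm = c(3, 3, 3), nuisance_scale = 1,
                       n_perm = 500L, alpha = 0.05, tfce_e = 0.5,
                       tfce_h = 2.0, connectivity = 26L,
                       group_smooth_fwhm_mm = 6.3,
                       mask_source = c("young", "older-negative"),
                       families = c("age", "stage", "associations",
                                    "converter", "gam_ranked"),
                       fd_adjust = FALSE, both_networks = FALSE,
                       output_dir = tempfile("mtlnet_run_")) {
  mode <- match.arg(mode)
  mask_source <- match.arg(mask_source)
  stopifnot(n_subjects >= 1L, n_perm >= 1L, alpha > 0, alpha < 1)
  structure(list(mode = mode, seed = as.integer(seed), cohort = cohort,
                 n_subjects = as.integer(n_subjects), loadings = loadings,
                 n_volumes = as.integer(n_volumes), tr_s = tr_s,
                 grid_shape = as.integer(grid_shape),
                 voxel_size_mm = voxel_size_mm,
                 nuisance_scale = nuisance_scale,
                 n_perm = as.integer(n_perm), alpha = alpha,
                 tfce_e = tfce_e, tfce_h = tfce_h,
                 connectivity = as.integer(connectivity),
                 group_smooth_fwhm_mm = group_smooth_fwhm_mm,
                 mask_source = mask_source, families = families,
                 fd_adjust = fd_adjust, both_networks = both_networks,
                 output_dir = output_dir),
            class = "run_config")
}

stage_seed <- function(config, offset) (config$seed * 1009L + offset) %% 2147483647L

#' Execute the full pipeline
#'
#' Table mode runs generator -> statistics suite; image mode runs generator
#' -> preprocessing (bandpass, confound regression) -> seed connectivity ->
#' permutation inference with TFCE/FWE -> mask building -> index extraction,
#' and reports Dice overlap between recovered and planted networks.  All
#' outputs (cohort TSV, results TSV, masks as NIfTI, JSON manifest) are
#' written under `config$output_dir`.
#'
#' @param config a [run_config()].
#' @return Invisibly, a list with the run artifacts (`manifest`, plus
#'   mode-specific elements: `results`/`fits` in table mode; `masks`,
#'   `dice_at`, `dice_pm`, `indexes` in image mode).
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(mode = config$mode, seed = config$seed,
                   config = config[setdiff(names(config), "cohort")],
                   stages = list())
  out <- list()
  if (config$mode == "table") {
    gen <- generate_cohort(config$cohort, seed = stage_seed(config, 1L))
    write_cohort(gen$cohort, file.path(config$output_dir, "cohort.tsv"))
    manifest$stages$synthgen <- list(n_rows = nrow(gen$cohort),
                                     n_subjects = length(unique(gen$cohort$subject_id)),
                                     seed = stage_seed(config, 1L))
    suite <- run_analysis_suite(gen$cohort, families = config$families,
                                fd_adjust = config$fd_adjust,
                                both_networks = config$both_networks)
    utils::write.table(suite$results,
                       file.path(config$output_dir, "results.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$stages$stats <- list(n_designs = nrow(suite$results))
    out <- list(cohort = gen$cohort, truth = gen$truth,
                results = suite$results, fits = suite$fits)
  } else {
    out <- run_image_pipeline(config, manifest)
    manifest <- out$manifest
  }
  manifest_path <- file.path(config$output_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, null = "null", force = TRUE)
  out$manifest <- manifest
  invisible(out)
}

run_image_pipeline <- function(config, manifest) {
  grid <- volume_grid(config$grid_shape, config$voxel_size_mm)
  lay <- roi_layout(grid)
  prc_maps <- list(); phc_maps <- list(); qc_log <- list()
  seg1 <- NULL
  for (i in seq_len(config$n_subjects)) {
    gen <- generate_run(config$loadings, grid, config$n_volumes, config$tr_s,
                        seed = stage_seed(config, 100L + i),
                        nuisance_scale = config$nuisance_scale,
                        subject_id = sprintf("S%04d", i))
    if (is.null(seg1)) seg1 <- gen$seg
    qc <- motion_qc(gen$motion)
    qc_log[[i]] <- data.frame(subject_id = gen$run$subject_id,
                              decision = qc$decision,
                              reasons = paste(qc$reasons, collapse = ";"),
                              stringsAsFactors = FALSE)
    if (qc$decision == "exclude") next
    run <- bandpass(gen$run)
    conf <- extract_confounds(run, gen$seg, gen$motion)
    conf <- filter_confounds(conf, run$tr_s)
    run <- nuisance_regression(run, conf)
    amask <- dropout_mask(gen$seg$gm_t1, gen$seg$gm_t2star)
    zp <- fisher_z(seed_correlation_map(run, gen$seeds$prc, amask, "PRC"))
    zh <- fisher_z(seed_correlation_map(run, gen$seeds$phc, amask, "PHC"))
    if (config$group_smooth_fwhm_mm > 0) {
      prc_maps[[length(prc_maps) + 1L]] <-
        gaussian_smooth(zp, config$group_smooth_fwhm_mm)
      phc_maps[[length(phc_maps) + 1L]] <-
        gaussian_smooth(zh, config$group_smooth_fwhm_mm)
    } else {
      prc_maps[[length(prc_maps) + 1L]] <- zp
      phc_maps[[length(phc_maps) + 1L]] <- zh
    }
  }
  qc_df <- do.call(rbind, qc_log)
  utils::write.table(qc_df, file.path(config$output_dir, "qc_log.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  manifest$stages$preprocess <- list(
    n_generated = config$n_subjects,
    n_retained = length(prc_maps),
    excluded = qc_df$subject_id[qc_df$decision == "exclude"])
  if (length(prc_maps) < 5L) stop("image pipeline: fewer than 5 runs retained")

  amask <- dropout_mask(seg1$gm_t1, seg1$gm_t2star)
  pt <- function(test, s, ...) test(..., analysis_mask = amask,
                                    n_perm = config$n_perm,
                                    alpha = config$alpha,
                                    seed = stage_seed(config, s),
                                    E = config$tfce_e, H = config$tfce_h,
                                    connectivity = config$connectivity)
  prc_os <- pt(one_sample_perm_test, 11L, prc_maps)
  phc_os <- pt(one_sample_perm_test, 12L, phc_maps)
  prc_gt <- pt(paired_perm_test, 13L, prc_maps, phc_maps)
  phc_gt <- pt(paired_perm_test, 14L, phc_maps, prc_maps)
  masks <- build_network_masks(prc_os, phc_os, prc_gt, phc_gt)
  write_volume(masks$at_mask, file.path(config$output_dir, "at_mask.nii.gz"))
  write_volume(masks$pm_mask, file.path(config$output_dir, "pm_mask.nii.gz"))

  planted_at <- new_volume(as.numeric(lay$at), grid)
  planted_pm <- new_volume(as.numeric(lay$pm), grid)
  # recovery is judged on the masks actually used downstream: group mask
  # within grey matter with seed voxels removed (the seeds are trivially
  # seed-connected and never part of the planted networks)
  seed_vols <- list(new_volume(as.numeric(lay$seed_prc), grid),
                    new_volume(as.numeric(lay$seed_phc), grid))
  d_at <- dice(participant_mask(masks$at_mask, seg1$gm_t1, seeds = seed_vols),
               planted_at)
  d_pm <- dice(participant_mask(masks$pm_mask, seg1$gm_t1, seeds = seed_vols),
               planted_pm)
  manifest$stages$netmask <- list(
    n_perm = config$n_perm, alpha = config$alpha,
    at_voxels = sum(masks$at_mask), pm_voxels = sum(masks$pm_mask),
    dice_at_vs_planted = d_at, dice_pm_vs_planted = d_pm)

  # participant-specific extraction from unsmoothed maps
  idx <- list()
  for (i in seq_along(prc_maps)) {
    zp <- prc_maps[[i]]; zh <- phc_maps[[i]]
    pm_at <- participant_mask(masks$at_mask, seg1$gm_t1,
                              seeds = list(new_volume(as.numeric(lay$seed_prc), grid),
                                           new_volume(as.numeric(lay$seed_phc), grid)))
    pm_pm <- participant_mask(masks$pm_mask, seg1$gm_t1,
                              seeds = list(new_volume(as.numeric(lay$seed_prc), grid),
                                           new_volume(as.numeric(lay$seed_phc), grid)))
    unsm_p <- if (is.null(zp$smoothed_fwhm_mm)) zp else NULL
    unsm_h <- if (is.null(zh$smoothed_fwhm_mm)) zh else NULL
    idx[[i]] <- data.frame(
      subject_id = zp$subject_id,
      at_index = if (!is.null(unsm_p)) positive_mean(unsm_p, pm_at) else NA_real_,
      pm_index = if (!is.null(unsm_h)) positive_mean(unsm_h, pm_pm) else NA_real_,
      stringsAsFactors = FALSE)
  }
  indexes <- do.call(rbind, idx)
  utils::write.table(indexes, file.path(config$output_dir, "indexes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  list(manifest = manifest, masks = masks, dice_at = d_at, dice_pm = d_pm,
       indexes = indexes,
       perm_results = list(prc_onesample = prc_os, phc_onesample = phc_os,
                           prc_gt_phc = prc_gt, phc_gt_prc = phc_gt))
}

#' Validate a set of pipeline input files
#'
#' Checks that all NIfTI volumes share one grid, that a motion TSV has six
#' columns and one row per BOLD volume, and that a cohort TSV carries the
#' expected column schema.
#'
#' @param nifti_paths character vector of NIfTI file paths (the first 4D file
#'   defines the volume count for the motion check).
#' @param motion_path optional motion TSV path.
#' @param cohort_path optional cohort TSV path.
#' @return Character vector of problems; empty when everything matches.
#' @export
validate_inputs <- function(nifti_paths = character(), motion_path = NULL,
                            cohort_path = NULL) {
  problems <- character()
  grids <- list(); n_vols <- NA_integer_
  for (p in nifti_paths) {
    v <- tryCatch(read_volume(p), error = function(e) e)
    if (inherits(v, "error")) {
      problems <- c(problems, sprintf("%s: unreadable (%s)", p,
                                      conditionMessage(v)))
      next
    }
    grids[[p]] <- attr(v, "grid")
    if (length(dim(v)) == 4L && is.na(n_vols)) n_vols <- dim(v)[4]
  }
  if (length(grids) > 1L) {
    ref <- grids[[1]]
    for (p in names(grids)[-1]) {
      if (!grids_equal(ref, grids[[p]]))
        problems <- c(problems, sprintf(
          "grid mismatch: %s is %s voxels but %s is %s voxels",
          names(grids)[1], paste(ref$shape, collapse = "x"),
          p, paste(grids[[p]]$shape, collapse = "x")))
    }
  }
  if (!is.null(motion_path)) {
    m <- tryCatch(read_motion(motion_path), error = function(e) NULL)
    if (is.null(m)) {
      problems <- c(problems, sprintf("%s: unreadable motion TSV", motion_path))
    } else {
      if (ncol(m) != 6L)
        problems <- c(problems, sprintf("%s: expected 6 motion columns, got %d",
                                        motion_path, ncol(m)))
      if (!is.na(n_vols) && nrow(m) != n_vols)
        problems <- c(problems, sprintf(
          "%s: %d motion rows but %d BOLD volumes", motion_path, nrow(m),
          n_vols))
    }
  }
  if (!is.null(cohort_path)) {
    cb <- tryCatch(read_cohort(cohort_path), error = function(e) NULL)
    need <- c("subject_id", "visit_index", "group", "age_years", "sex",
              "education_years", "months_from_baseline")
    if (is.null(cb)) {
      problems <- c(problems, sprintf("%s: unreadable cohort TSV", cohort_path))
    } else {
      miss <- setdiff(need, names(cb))
      if (length(miss))
        problems <- c(problems, sprintf("%s: missing column(s) %s", cohort_path,
                                        paste(miss, collapse = ", ")))
    }
  }
  problems
}
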