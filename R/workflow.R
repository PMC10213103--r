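#' Study configuration for the five workflow analyses
#'
#' Holds the phantom presets, seeds and condition grids used throughout the
#' workflow commands. The condition defaults mirror the study design:
#' imaging energies 40/50/60 kV, bin widths 10/25/50/100, slice thicknesses
#' 0.2/0.26/0.3/0.5/1 mm, segmentation volumes 27.68/34.38/41.71/92.24/237.5
#' mm^3, and the recommended workflow (60 kV, bin width 25, 0.26 mm) as the
#' default extraction setting. Subjects for phantom ICCs are repeated seeded
#' ROI placements within the soft-tissue compartment.
#'
#' @param seed master seed; every random draw in a run derives from it.
#' @param grid_shape,spacing mouse-phantom grid (voxels, mm).
#' @param energies,bin_widths,slice_thicknesses,volumes condition grids.
#' @param roi_count ROI placements per condition (the ICC subjects).
#' @param roi_volume sphere volume (mm^3) for the repeatability sweeps.
#' @param texture_volume sphere volume (mm^3) for the texture study.
#' @param texture_grid_shape,texture_spacing texture-phantom grid.
#' @param cohort_grid_shape cohort subject grid (at `spacing`).
#' @param n_subjects subjects per cohort arm.
#' @param effect_size cohort separation in texture-sd units.
#' @param default_energy,default_bin_width,default_slice the fixed workflow
#'   settings used while one variable is swept.
#' @param wavelet extract wavelet-filtered features (turning this off
#'   restricts all analyses to the 106 original-image features).
#' @param noise_scale multiplier applied to every protocol's noise and bias
#'   amplitudes (1 = the preset protocols; 0 = noiseless scans for
#'   degenerate-case studies).
#' @return An object of class `study_config`.
#' @export
study_config <- function(seed = 1234L,
                         grid_shape = c(64L, 64L, 64L), spacing = 0.26,
                         energies = c(40, 50, 60),
                         bin_widths = c(10, 25, 50, 100),
                         slice_thicknesses = c(0.2, 0.26, 0.3, 0.5, 1.0),
                         volumes = c(27.68, 34.38, 41.71, 92.24, 237.5),
                         roi_count = 10L, roi_volume = 92.24,
                         texture_volume = 41.71,
                         texture_grid_shape = c(120L, 120L, 120L),
                         texture_spacing = 0.5,
                         cohort_grid_shape = c(40L, 40L, 40L),
                         n_subjects = 9L, effect_size = 2,
                         default_energy = 60, default_bin_width = 25,
                         default_slice = 0.26, wavelet = TRUE,
                         noise_scale = 1) {
  if (!is.finite(noise_scale) || noise_scale < 0)
    stop("study_config: noise_scale must be >= 0")
  stopifnot(length(energies) >= 1L, length(bin_widths) >= 1L,
            length(slice_thicknesses) >= 1L, length(volumes) >= 1L,
            roi_count >= 2L)
  structure(list(
    seed = as.integer(seed), grid_shape = as.integer(grid_shape),
    spacing = spacing, energies = energies, bin_widths = bin_widths,
    slice_thicknesses = slice_thicknesses, volumes = volumes,
    roi_count = as.integer(roi_count), roi_volume = roi_volume,
    texture_volume = texture_volume,
    texture_grid_shape = as.integer(texture_grid_shape),
    texture_spacing = texture_spacing,
    cohort_grid_shape = as.integer(cohort_grid_shape),
    n_subjects = as.integer(n_subjects), effect_size = effect_size,
    default_energy = default_energy,
    default_bin_width = default_bin_width,
    default_slice = default_slice, wavelet = isTRUE(wavelet),
    noise_scale = noise_scale),
    class = "study_config")
}

#' Load a study configuration from a YAML file
#' @param path YAML file whose keys match [study_config()] arguments.
#' @return A `study_config`.
#' @export
study_config_from_yaml <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("study_config_from_yaml requires the yaml package")
  do.call(study_config, yaml::yaml.load_file(path))
}

mouse_grid <- function(config) {
  grid_spec(config$grid_shape, config$spacing)
}

# energy preset with the config's noise scaling applied
config_protocol <- function(config, energy) {
  p <- scan_protocol(energy)
  scan_protocol(energy,
                noise_sd = p$noise_sd * config$noise_scale,
                contrast_scale = p$contrast_scale,
                bias_amplitude = p$bias_amplitude * config$noise_scale)
}

#' Place spherical ROIs inside a labelled compartment
#'
#' Rejection-samples sphere centres among voxels of the target label until
#' `count` spheres lie entirely within the compartment. Deterministic given
#' the seed; fails with an informative error when the compartment cannot
#' host the requested spheres.
#'
#' @param labels integer label array (from a phantom generator).
#' @param grid the matching [grid_spec()].
#' @param volume sphere volume, mm^3.
#' @param count number of placements.
#' @param seed integer seed.
#' @param label target compartment label (1 = mouse soft tissue).
#' @param max_tries rejection-sampling cap.
#' @return List of `count` [roi_mask()]s.
#' @export
place_roi_spheres <- function(labels, grid, volume, count, seed = 1L,
                              label = 1L, max_tries = 4000L) {
  r <- (3 * volume / (4 * pi))^(1 / 3)
  rv <- ceiling(r / grid$spacing)
  off <- as.matrix(expand.grid(x = -rv[1]:rv[1], y = -rv[2]:rv[2],
                               z = -rv[3]:rv[3]))
  keep <- (off[, 1] * grid$spacing[1])^2 + (off[, 2] * grid$spacing[2])^2 +
    (off[, 3] * grid$spacing[3])^2 <= r^2
  off <- off[keep, , drop = FALSE]
  cand <- which(labels == label, arr.ind = TRUE)
  ok_margin <- cand[, 1] > rv[1] & cand[, 1] <= dim(labels)[1] - rv[1] &
    cand[, 2] > rv[2] & cand[, 2] <= dim(labels)[2] - rv[2] &
    cand[, 3] > rv[3] & cand[, 3] <= dim(labels)[3] - rv[3]
  cand <- cand[ok_margin, , drop = FALSE]
  if (nrow(cand) == 0L)
    stop("place_roi_spheres: no candidate centre leaves room for a ",
         signif(volume, 4), " mm^3 sphere in compartment ", label)
  set.seed(seed)
  ord <- sample.int(nrow(cand))
  masks <- list()
  tries <- 0L
  for (i in ord) {
    tries <- tries + 1L
    if (tries > max_tries) break
    ctr <- cand[i, ]
    vox <- cbind(ctr[1] + off[, 1], ctr[2] + off[, 2], ctr[3] + off[, 3])
    if (all(labels[vox] == label)) {
      centre_mm <- grid$origin + (ctr - 1) * grid$spacing
      masks[[length(masks) + 1L]] <-
        make_spherical_mask(grid, centre_mm, volume)
      if (length(masks) == count) break
    }
  }
  if (length(masks) < count)
    stop("place_roi_spheres: only ", length(masks), " of ", count,
         " spheres of ", signif(volume, 4),
         " mm^3 fit in compartment ", label, " after ", tries, " tries")
  masks
}

# long feature table for scan/rescan pairs of one condition
pair_feature_table <- function(pair, masks, config_ex, condition) {
  fs <- extract_multi(pair$scan, masks, config_ex)
  fr <- extract_multi(pair$rescan, masks, config_ex)
  rbind(
    feature_long(fs, roi_id = seq_along(masks), condition = condition,
                 replicate = "scan"),
    feature_long(fr, roi_id = seq_along(masks), condition = condition,
                 replicate = "rescan"))
}

# shared scan/rescan feature tables for the repeatability sweeps
repeatability_tables <- function(config,
                                 variable = c("energy", "bin_width",
                                              "slice_thickness")) {
  variable <- match.arg(variable)
  grid <- mouse_grid(config)
  phantom <- generate_mouse_phantom(grid, seed = config$seed)
  masks <- place_roi_spheres(phantom$labels, grid, config$roi_volume,
                             config$roi_count,
                             seed = config$seed + 101L)
  seeds <- draw_subseeds(config$seed + 7L, 2L * 8L)
  base_ex <- function(bw = config$default_bin_width,
                      st = config$default_slice)
    extraction_config(bin_width = bw, slice_thickness = st,
                      wavelet = config$wavelet)
  tabs <- list()
  if (variable == "energy") {
    for (i in seq_along(config$energies)) {
      e <- config$energies[i]
      pair <- simulate_scan_pair(phantom$image, config_protocol(config, e),
                                 seeds = seeds[c(2 * i - 1, 2 * i)])
      tabs[[i]] <- pair_feature_table(pair, masks, base_ex(),
                                      condition = paste0(e, "kV"))
    }
  } else {
    pair <- simulate_scan_pair(phantom$image,
                               config_protocol(config, config$default_energy),
                               seeds = seeds[1:2])
    conds <- if (variable == "bin_width") config$bin_widths
             else config$slice_thicknesses
    for (i in seq_along(conds)) {
      ex <- if (variable == "bin_width") base_ex(bw = conds[i])
            else base_ex(st = conds[i])
      lab <- if (variable == "bin_width") paste0("bw", conds[i])
             else paste0("st", conds[i])
      tabs[[i]] <- pair_feature_table(pair, masks, ex, condition = lab)
    }
  }
  do.call(rbind, tabs)
}

#' Repeatability sweep: scan-rescan ICC per condition
#'
#' Simulates scan-rescan pairs of the mouse phantom under one swept variable
#' (imaging energy, bin width or slice thickness; the other settings stay at
#' the recommended workflow values), extracts the full feature vector for
#' each seeded ROI placement, and screens every feature's single-measures
#' absolute-agreement ICC per condition. Reports per-condition robust counts
#' and the all-condition robust intersection.
#'
#' @param config a [study_config()].
#' @param variable which parameter to sweep.
#' @param outdir optional directory for CSV output (records, intersections,
#'   long table and a JSON run manifest).
#' @return List with `report` (a `reliability_report`), `table` (the long
#'   feature table) and `variable`.
#' @export
run_repeatability <- function(config = study_config(),
                              variable = c("energy", "bin_width",
                                           "slice_thickness"),
                              outdir = NULL) {
  variable <- match.arg(variable)
  tbl <- repeatability_tables(config, variable)
  if (length(unique(tbl$condition)) < 2L)
    warning("single condition: intersection report is trivial")
  report <- screen_features(tbl)
  res <- list(report = report, table = tbl, variable = variable)
  if (!is.null(outdir))
    write_workflow_outputs(res, config, outdir,
                           prefix = paste0("repeatability_", variable))
  res
}

#' Volume effect: reliability and volume correlation across segmentation sizes
#'
#' Screens scan-rescan repeatability at each of the study's segmentation
#' volumes, then correlates each original-image (unfiltered) feature's
#' volume-condition mean against the measured `original_shape_MeshVolume`,
#' flagging features with Pearson r > 0.8.
#'
#' @inheritParams run_repeatability
#' @return List with `report`, `correlation` (volume-correlation
#'   data.frame), `table`.
#' @export
run_volume_effect <- function(config = study_config(), outdir = NULL) {
  grid <- mouse_grid(config)
  phantom <- generate_mouse_phantom(grid, seed = config$seed)
  seeds <- draw_subseeds(config$seed + 13L, 2L)
  pair <- simulate_scan_pair(phantom$image,
                             config_protocol(config, config$default_energy),
                             seeds = seeds)
  ex <- extraction_config(bin_width = config$default_bin_width,
                          slice_thickness = config$default_slice,
                          wavelet = config$wavelet)
  tabs <- list()
  for (i in seq_along(config$volumes)) {
    v <- config$volumes[i]
    masks <- tryCatch(
      place_roi_spheres(phantom$labels, grid, v, config$roi_count,
                        seed = config$seed + 200L + i),
      error = function(e) {
        warning("volume ", v, " mm^3 skipped: ", conditionMessage(e))
        NULL
      })
    if (is.null(masks)) next
    tabs[[length(tabs) + 1L]] <-
      pair_feature_table(pair, masks, ex, condition = paste0(v, "mm3"))
  }
  if (!length(tabs)) stop("run_volume_effect: no volume could be placed")
  tbl <- do.call(rbind, tabs)
  report <- screen_features(tbl)
  # per-volume mean of every original feature, correlated against the
  # measured mesh volume
  orig <- tbl[startsWith(tbl$feature_name, "original_"), ]
  agg <- stats::aggregate(value ~ condition + feature_name, data = orig,
                          FUN = mean)
  mesh <- agg[agg$feature_name == "original_shape_MeshVolume", ]
  vol_of <- stats::setNames(mesh$value, mesh$condition)
  corr_tbl <- data.frame(feature_name = agg$feature_name,
                         volume = vol_of[agg$condition],
                         value = agg$value)
  correlation <- volume_correlation(corr_tbl)
  res <- list(report = report, correlation = correlation, table = tbl)
  if (!is.null(outdir)) {
    write_workflow_outputs(res, config, outdir, prefix = "volume_effect")
    utils::write.csv(correlation,
                     file.path(outdir, "volume_effect_correlation.csv"),
                     row.names = FALSE)
  }
  res
}

#' Reproducibility: average-measures ICC across conditions
#'
#' Averages scan and rescan per ROI and condition, then computes the
#' average-measures absolute-agreement ICC per feature with the swept
#' conditions as raters.
#'
#' @inheritParams run_repeatability
#' @param table optional precomputed long table from [run_repeatability()]
#'   (avoids re-simulating).
#' @return List with `report` and `table`.
#' @export
run_reproducibility <- function(config = study_config(),
                                variable = c("energy", "bin_width",
                                             "slice_thickness"),
                                table = NULL, outdir = NULL) {
  variable <- match.arg(variable)
  tbl <- table %||% repeatability_tables(config, variable)
  report <- reproducibility_screen(tbl)
  res <- list(report = report, table = tbl, variable = variable)
  if (!is.null(outdir))
    write_workflow_outputs(res, config, outdir,
                           prefix = paste0("reproducibility_", variable))
  res
}

#' Texture study: feature variability across material densities
#'
#' Extracts features from fixed-volume spheres placed in each insert of the
#' texture phantom and in the mouse soft tissue, under scan-rescan at the
#' default energy; reports per-material mean intensity
#' (`original_firstorder_Mean`), per-material scan-rescan reliability, and
#' the NGTDM feature table.
#'
#' @inheritParams run_repeatability
#' @return List with `mean_intensity` (material table), `report`,
#'   `ngtdm` (material x NGTDM means), `table`.
#' @export
run_texture_study <- function(config = study_config(), outdir = NULL) {
  tgrid <- grid_spec(config$texture_grid_shape, config$texture_spacing)
  tp <- generate_texture_phantom(tgrid, seed = config$seed)
  seeds <- draw_subseeds(config$seed + 23L, 4L)
  proto <- config_protocol(config, config$default_energy)
  tpair <- simulate_scan_pair(tp$image, proto, seeds = seeds[1:2])
  ex <- extraction_config(bin_width = config$default_bin_width,
                          slice_thickness = NULL,
                          wavelet = config$wavelet)
  tabs <- list()
  for (k in seq_along(tp$insert_names)) {
    masks <- place_roi_spheres(tp$labels, tgrid, config$texture_volume,
                               config$roi_count,
                               seed = config$seed + 300L + k, label = k)
    tabs[[k]] <- pair_feature_table(tpair, masks, ex,
                                    condition = tp$insert_names[k])
  }
  mgrid <- mouse_grid(config)
  mp <- generate_mouse_phantom(mgrid, seed = config$seed)
  mpair <- simulate_scan_pair(mp$image, proto, seeds = seeds[3:4])
  mex <- extraction_config(bin_width = config$default_bin_width,
                           slice_thickness = config$default_slice,
                           wavelet = config$wavelet)
  mmasks <- place_roi_spheres(mp$labels, mgrid, config$texture_volume,
                              config$roi_count,
                              seed = config$seed + 310L)
  tabs[[length(tabs) + 1L]] <-
    pair_feature_table(mpair, mmasks, mex, condition = "mouse_soft_tissue")
  tbl <- do.call(rbind, tabs)
  report <- screen_features(tbl)
  mean_tbl <- stats::aggregate(
    value ~ condition,
    data = tbl[tbl$feature_name == "original_firstorder_Mean", ],
    FUN = mean)
  names(mean_tbl) <- c("material", "original_firstorder_Mean")
  ngtdm <- stats::aggregate(
    value ~ condition + feature_name,
    data = tbl[grepl("^original_ngtdm_", tbl$feature_name), ],
    FUN = mean)
  names(ngtdm) <- c("material", "feature_name", "value")
  res <- list(mean_intensity = mean_tbl, report = report, ngtdm = ngtdm,
              table = tbl)
  if (!is.null(outdir)) {
    write_workflow_outputs(res, config, outdir, prefix = "texture")
    utils::write.csv(mean_tbl, file.path(outdir, "texture_mean_intensity.csv"),
                     row.names = FALSE)
    utils::write.csv(ngtdm, file.path(outdir, "texture_ngtdm.csv"),
                     row.names = FALSE)
  }
  res
}

#' Cohort pilot: robust-feature differentiation between two tumour arms
#'
#' Generates the two synthetic cohorts, simulates a scan-rescan pair per
#' subject, screens per-cohort scan-rescan reliability (subjects as ICC
#' subjects), intersects the two arms' robust sets (optionally also with an
#' externally supplied robust set, e.g. from the phantom repeatability
#' study), and tests the surviving features with a paired two-tailed t-test
#' at p < 0.05.
#'
#' @inheritParams run_repeatability
#' @param robust_set optional character vector restricting the tested
#'   features.
#' @return List with `report`, `tested` (feature names), `comparison`
#'   (per-feature t/p), `significant` (feature names), `table`.
#' @export
run_cohort_pilot <- function(config = study_config(), robust_set = NULL,
                             outdir = NULL) {
  grid <- grid_spec(config$cohort_grid_shape, config$spacing)
  specs <- cohort_pair_specs(config$effect_size, config$n_subjects)
  subjects <- generate_tumour_cohort(specs$A, specs$B, grid,
                                     seed = config$seed + 41L)
  proto <- config_protocol(config, config$default_energy)
  seeds <- draw_subseeds(config$seed + 43L, 2L * length(subjects))
  ex <- extraction_config(bin_width = config$default_bin_width,
                          slice_thickness = config$default_slice,
                          wavelet = config$wavelet, shape = FALSE)
  rows <- list()
  for (i in seq_along(subjects)) {
    s <- subjects[[i]]
    pair <- simulate_scan_pair(s$image, proto,
                               seeds = seeds[c(2 * i - 1, 2 * i)])
    fv <- extract_multi(pair$scan, list(s$mask), ex)[[1]]
    fr <- extract_multi(pair$rescan, list(s$mask), ex)[[1]]
    rows[[length(rows) + 1L]] <- data.frame(
      roi_id = i, condition = s$cohort, replicate = "scan",
      feature_name = names(fv), value = unname(fv),
      subject = ((i - 1L) %% config$n_subjects) + 1L)
    rows[[length(rows) + 1L]] <- data.frame(
      roi_id = i, condition = s$cohort, replicate = "rescan",
      feature_name = names(fr), value = unname(fr),
      subject = ((i - 1L) %% config$n_subjects) + 1L)
  }
  tbl <- do.call(rbind, rows)
  report <- screen_features(tbl)
  tested <- Reduce(intersect, report$robust_sets)
  if (!is.null(robust_set)) tested <- intersect(tested, robust_set)
  if (!length(tested)) {
    comparison <- data.frame(feature_name = character(), mean_diff = numeric(),
                             t = numeric(), p = numeric(),
                             significant = logical())
    message("run_cohort_pilot: no testable robust features")
  } else {
    agg <- stats::aggregate(value ~ condition + subject + feature_name,
                            data = tbl, FUN = mean)
    names(agg)[names(agg) == "condition"] <- "cohort"
    comparison <- compare_cohorts(agg, robust_set = tested)
  }
  res <- list(report = report, tested = tested, comparison = comparison,
              significant = comparison$feature_name[comparison$significant],
              table = tbl)
  if (!is.null(outdir)) {
    write_workflow_outputs(res, config, outdir, prefix = "cohort")
    utils::write.csv(comparison, file.path(outdir, "cohort_comparison.csv"),
                     row.names = FALSE)
  }
  res
}

#' Materialise the preset fixtures on disk
#'
#' Writes the default mouse phantom, texture phantom (image + label map,
#' NIfTI and NRRD) and one tumour-cohort subject per arm to `outdir`.
#'
#' @param outdir output directory (created if needed).
#' @param seed master seed.
#' @param grid mouse-phantom [grid_spec()].
#' @return Invisibly, the written paths.
#' @export
write_fixtures <- function(outdir, seed = 1234L,
                           grid = grid_spec(c(64L, 64L, 64L), 0.26)) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  mp <- generate_mouse_phantom(grid, seed = seed)
  tg <- grid_spec(c(120L, 120L, 120L), 0.5)
  tp <- generate_texture_phantom(tg, seed = seed)
  save_pair <- function(obj, grid_used, stem) {
    p1 <- file.path(outdir, paste0(stem, ".nii.gz"))
    p2 <- file.path(outdir, paste0(stem, ".nrrd"))
    write_volume(obj$image, p1)
    write_volume(obj$image, p2)
    lab <- roi_mask(obj$labels > 0, spacing = grid_used$spacing,
                    origin = grid_used$origin)
    p3 <- file.path(outdir, paste0(stem, "_body_mask.nii.gz"))
    write_mask(lab, p3)
    c(p1, p2, p3)
  }
  paths <- c(paths, save_pair(mp, grid, "mouse_phantom"),
             save_pair(tp, tg, "texture_phantom"))
  specs <- cohort_pair_specs()
  cg <- grid_spec(c(40L, 40L, 40L), 0.26)
  subj <- generate_tumour_cohort(specs$A, specs$B, cg, seed = seed)
  for (s in subj[c(1, specs$A$n_subjects + 1)]) {
    stem <- file.path(outdir, paste0("cohort_", gsub("[^A-Za-z0-9]", "",
                                                     s$cohort)))
    write_volume(s$image, paste0(stem, ".nii.gz"))
    write_mask(s$mask, paste0(stem, "_mask.nii.gz"))
    paths <- c(paths, paste0(stem, ".nii.gz"), paste0(stem, "_mask.nii.gz"))
  }
  invisible(paths)
}

write_workflow_outputs <- function(res, config, outdir, prefix) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(res$report$records,
                   file.path(outdir, paste0(prefix, "_records.csv")),
                   row.names = FALSE)
  utils::write.csv(res$report$intersections,
                   file.path(outdir, paste0(prefix, "_intersections.csv")),
                   row.names = FALSE)
  utils::write.csv(res$table,
                   file.path(outdir, paste0(prefix, "_features_long.csv")),
                   row.names = FALSE)
  manifest <- list(
    prefix = prefix,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    package_version = as.character(utils::packageVersion("cbctradiomics")),
    config = unclass(config))
  jsonlite::write_json(manifest,
                       file.path(outdir, paste0(prefix, "_manifest.json")),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(NULL)
}
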