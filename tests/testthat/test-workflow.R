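# Scaled-down study configurations keep these end-to-end runs light; the
# condition grids themselves stay at the study defaults unless the test is
# specifically about a reduced grid.

small_cfg <- function(...) {
  study_config(seed = 42L, roi_count = 3L, roi_volume = 41.71,
               wavelet = FALSE, n_subjects = 3L, ...)
}

test_that("repeatability sweep reports per-condition ICCs and intersections", {
  cfg <- small_cfg(energies = c(50, 60))
  res <- run_repeatability(cfg, "energy")
  expect_s3_class(res$report, "reliability_report")
  expect_setequal(unique(res$table$condition), c("50kV", "60kV"))
  expect_identical(sort(unique(res$table$replicate)), c("rescan", "scan"))
  # 106 features x 3 ROIs x 2 replicates x 2 conditions
  expect_identical(nrow(res$table), 106L * 3L * 2L * 2L)
  expect_true("50kV+60kV" %in% res$report$intersections$condition_set)
})

test_that("fixed seeds give byte-identical workflow CSV output", {
  cfg <- small_cfg(energies = c(60))
  d1 <- file.path(tempdir(), "runA")
  d2 <- file.path(tempdir(), "runB")
  suppressWarnings({
    run_repeatability(cfg, "energy", outdir = d1)
    run_repeatability(cfg, "energy", outdir = d2)
  })
  f1 <- file.path(d1, "repeatability_energy_records.csv")
  f2 <- file.path(d2, "repeatability_energy_records.csv")
  expect_true(file.exists(f1))
  expect_identical(readLines(f1), readLines(f2))
  l1 <- file.path(d1, "repeatability_energy_features_long.csv")
  l2 <- file.path(d2, "repeatability_energy_features_long.csv")
  expect_identical(readLines(l1), readLines(l2))
  # emitted CSVs round-trip into the screening schema
  back <- utils::read.csv(l1)
  rep2 <- screen_features(back)
  expect_s3_class(rep2, "reliability_report")
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("zero-noise studies make every non-degenerate feature robust", {
  cfg <- small_cfg(noise_scale = 0)
  res <- run_repeatability(cfg, "bin_width")
  rec <- res$report$records
  expect_true(all(rec$label[!rec$degenerate] == "robust"))
  expect_setequal(unique(rec$condition), c("bw10", "bw25", "bw50", "bw100"))
})

test_that("volume effect flags volume-driven features by the signed rule", {
  cfg <- small_cfg()
  res <- run_volume_effect(cfg)
  expect_identical(length(unique(res$table$condition)), 5L)
  corr <- res$correlation
  # only original (unfiltered) features enter the correlation table
  expect_true(all(startsWith(corr$feature_name, "original_")))
  # the mesh volume itself and the voxel volume are planted positive
  # controls: exactly volume-proportional
  expect_true(corr$flagged[corr$feature_name == "original_shape_MeshVolume"])
  expect_true(corr$flagged[corr$feature_name == "original_shape_VoxelVolume"])
  expect_false(any(corr$flagged[corr$degenerate]))
})

test_that("texture study orders material intensities by configuration", {
  cfg <- small_cfg(texture_grid_shape = c(64L, 64L, 64L),
                   texture_spacing = 0.5)
  res <- run_texture_study(cfg)
  mt <- res$mean_intensity
  expect_identical(nrow(mt), 5L)
  expect_setequal(mt$material,
                  c("air", "solid_water", "pvc", "acetal",
                    "mouse_soft_tissue"))
  means <- stats::setNames(mt$original_firstorder_Mean, mt$material)
  expect_identical(names(which.min(means)), "air")
  expect_gt(means[["mouse_soft_tissue"]], 15000)
  expect_identical(nrow(res$ngtdm), 5L * 5L)
  expect_identical(length(res$report$robust_sets), 5L)
})

test_that("NGTDM contrast vanishes on a noiseless homogeneous insert", {
  cfg <- small_cfg(texture_grid_shape = c(64L, 64L, 64L),
                   texture_spacing = 0.5, noise_scale = 0)
  tg <- grid_spec(cfg$texture_grid_shape, cfg$texture_spacing)
  flat <- list(
    air = material_spec("air", 0.0012, mean_intensity = 1861),
    solid_water = material_spec("solid_water", 1.05,
                                mean_intensity = 2940))
  tp <- generate_texture_phantom(tg, flat, seed = 1)
  pair <- simulate_scan_pair(tp$image,
                             scan_protocol(60, noise_sd = 0,
                                           bias_amplitude = 0))
  masks <- place_roi_spheres(tp$labels, tg, 41.71, 2, seed = 3, label = 2L)
  fv <- extract_all(pair$scan, masks[[1]],
                    extraction_config(slice_thickness = NULL,
                                      wavelet = FALSE, shape = FALSE))
  expect_equal(unname(fv["original_ngtdm_Contrast"]), 0)
  expect_equal(unname(fv["original_firstorder_Variance"]), 0)
})

test_that("cohort pilot separates arms at the configured effect size", {
  cfg <- small_cfg(effect_size = 4)
  res <- run_cohort_pilot(cfg)
  expect_identical(length(unique(res$table$roi_id)), 6L)
  expect_true(all(c("feature_name", "t", "p", "significant") %in%
                    names(res$comparison)))
  # the planted mean shift must surface in the first-order family
  expect_true(length(res$tested) > 0)
  sig <- res$significant
  expect_true(any(grepl("firstorder", sig)))
  expect_true("original_firstorder_Mean" %in% res$tested)
})

test_that("fixtures materialise and read back from disk", {
  out <- file.path(tempdir(), "fixtures")
  paths <- write_fixtures(out, seed = 1L,
                          grid = grid_spec(c(32L, 32L, 32L), 0.4))
  expect_true(all(file.exists(file.path(out, "mouse_phantom.nii.gz"))))
  img <- read_volume(file.path(out, "mouse_phantom.nrrd"))
  img2 <- read_volume(file.path(out, "mouse_phantom.nii.gz"))
  expect_equal(img$values, img2$values, tolerance = 1e-12)
  unlink(out, recursive = TRUE)
})
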