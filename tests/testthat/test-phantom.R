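grid64 <- grid_spec(c(64L, 64L, 64L), 0.26)

test_that("mouse phantom compartments follow the density calibration", {
  ph <- generate_mouse_phantom(grid64, seed = 7)
  expect_setequal(sort(unique(as.vector(ph$labels))), 0:3)
  m_soft <- mean(ph$image$values[ph$labels == 1L])
  m_lung <- mean(ph$image$values[ph$labels == 2L])
  m_bone <- mean(ph$image$values[ph$labels == 3L])
  expect_lt(m_lung, m_soft)
  expect_lt(m_soft, m_bone)
  expect_equal(m_soft, density_to_intensity(1.01), tolerance = 1e-6)
})

test_that("phantom generation is seed-deterministic", {
  a <- generate_mouse_phantom(grid64, seed = 11)
  b <- generate_mouse_phantom(grid64, seed = 11)
  c_ <- generate_mouse_phantom(grid64, seed = 12)
  expect_identical(a$image$values, b$image$values)
  expect_false(identical(a$image$values, c_$image$values))
  # noiseless generator ignores the seed entirely
  mats0 <- lapply(mouse_materials(), function(m) {
    m$texture_sd <- 0
    m
  })
  n1 <- generate_mouse_phantom(grid64, mats0, seed = 1)
  n2 <- generate_mouse_phantom(grid64, mats0, seed = 99)
  expect_identical(n1$image$values, n2$image$values)
})

test_that("within-material texture sd matches the configured sd", {
  ph <- generate_mouse_phantom(grid64, seed = 3)
  soft <- ph$image$values[ph$labels == 1L]
  expect_gt(length(soft), 5e4)
  expect_lt(abs(sd(soft) - 350) / 350, 0.02)
  air <- ph$image$values[ph$labels == 0L]
  expect_gt(length(air), 1e5)
  expect_lt(abs(sd(air) - 60) / 60, 0.02)
})

test_that("grid too small for the mouse geometry fails informatively", {
  expect_error(generate_mouse_phantom(grid_spec(c(6, 6, 6), 0.26)),
               "too small")
})

test_that("texture phantom builds disjoint labelled cylinders", {
  g <- grid_spec(c(80L, 80L, 80L), 0.5)
  tp <- generate_texture_phantom(g, seed = 5)
  expect_setequal(sort(unique(as.vector(tp$labels))), 0:4)
  means <- vapply(1:4, function(k) mean(tp$image$values[tp$labels == k]), 0)
  names(means) <- tp$insert_names
  expect_identical(names(which.min(means)), "air")
  # per-insert sample mean within 3 standard errors of the configured mean
  ins <- texture_inserts()
  for (k in seq_along(ins)) {
    vals <- tp$image$values[tp$labels == k]
    expect_gt(length(vals), 1e4)
    se <- sd(vals) / sqrt(length(vals) / 50)  # conservative for correlation
    expect_lt(abs(mean(vals) - ins[[k]]$mean_intensity), 3 * se + 1e-9)
  }
  # overlapping cylinders rejected
  expect_error(
    generate_texture_phantom(g, seed = 1, insert_radius = 12),
    "overlap|fit")
})

test_that("scan pairs share geometry and differ only by protocol noise", {
  ph <- generate_mouse_phantom(grid64, seed = 2)
  quiet <- scan_protocol(60, noise_sd = 0, bias_amplitude = 0)
  pr0 <- simulate_scan_pair(ph$image, quiet, seeds = c(5, 9))
  expect_identical(pr0$scan$values, pr0$rescan$values)
  pr <- simulate_scan_pair(ph$image, scan_protocol(60), seeds = c(1, 2))
  expect_false(identical(pr$scan$values, pr$rescan$values))
  expect_identical(dim(pr$scan$values), dim(pr$rescan$values))
  expect_equal(pr$scan$spacing, pr$rescan$spacing)
  expect_error(scan_protocol(60, noise_sd = -1), "noise_sd")
  expect_error(scan_protocol(45), "energy")
})

test_that("scan-difference noise sd recovers the configured protocol sd", {
  ph <- generate_mouse_phantom(grid64, seed = 2)
  est <- function(energy) {
    p <- scan_protocol(energy, bias_amplitude = 0)
    pr <- simulate_scan_pair(ph$image, p, seeds = c(21, 22))
    sd(pr$scan$values - pr$rescan$values) / sqrt(2)
  }
  e40 <- est(40)
  e60 <- est(60)
  expect_lt(abs(e40 - 300) / 300, 0.02)
  expect_lt(abs(e60 - 140) / 140, 0.02)
  expect_gt(e40, e60)
})

test_that("tumour cohorts deliver n subjects per arm with on-target masks", {
  g <- grid_spec(c(40L, 40L, 40L), 0.26)
  specs <- cohort_pair_specs(effect_size = 2, n_subjects = 9L)
  subj <- generate_tumour_cohort(specs$A, specs$B, g, seed = 4)
  expect_length(subj, 18L)
  labs <- vapply(subj, function(s) s$cohort, "")
  expect_identical(as.vector(table(labs)), c(9L, 9L))
  vols <- vapply(subj, function(s) mask_volume(s$mask), 0)
  expect_true(all(abs(vols - 94.25) / 94.25 < 0.05))
  # determinism
  subj2 <- generate_tumour_cohort(specs$A, specs$B, g, seed = 4)
  expect_identical(subj[[1]]$image$values, subj2[[1]]$image$values)
  # sphere must fit
  expect_error(
    generate_tumour_cohort(specs$A, specs$B, grid_spec(c(10, 10, 10), 0.26),
                           seed = 1),
    "fit")
  expect_error(cohort_spec("x", n_subjects = 1), "n_subjects")
})
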