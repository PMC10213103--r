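test_that("NIfTI and NRRD round-trips preserve values, spacing and origin", {
  set.seed(1)
  img <- voxel_image(array(rnorm(8^3, 1000, 50), c(8, 8, 8)),
                     spacing = c(0.5, 0.5, 1.0), origin = c(-1, 2, 3))
  for (ext in c(".nii.gz", ".nii", ".nrrd")) {
    path <- tempfile(fileext = ext)
    write_volume(img, path)
    back <- read_volume(path)
    expect_equal(back$values, img$values, tolerance = 1e-12)
    expect_equal(back$spacing, img$spacing, tolerance = 1e-12)
    expect_equal(back$origin, img$origin, tolerance = 1e-6)
    unlink(path)
  }
})

test_that("NRRD and NIfTI agree on the same data and masks stay binary", {
  set.seed(2)
  g <- grid_spec(c(10, 10, 10), 0.4)
  msk <- make_spherical_mask(g, c(0, 0, 0), 10)
  p1 <- tempfile(fileext = ".nii.gz")
  p2 <- tempfile(fileext = ".nrrd")
  write_mask(msk, p1)
  write_mask(msk, p2)
  m1 <- read_mask(p1)
  m2 <- read_mask(p2)
  expect_identical(m1$values, m2$values)
  # NIfTI stores pixdim as float32; agreement to single precision
  expect_equal(m1$spacing, m2$spacing, tolerance = 1e-6)
  expect_true(all(m1$values %in% c(0L, 1L)))
  unlink(c(p1, p2))
})

test_that("headers with missing or non-positive spacing are rejected", {
  path <- tempfile(fileext = ".nrrd")
  con <- file(path, "wb")
  writeLines(c("NRRD0004", "type: double", "dimension: 3", "sizes: 2 2 2",
               "space directions: (0,0,0) (0,1,0) (0,0,1)",
               "encoding: raw", "endian: little", ""), con)
  writeBin(rep(0, 8), con, size = 8, endian = "little")
  close(con)
  expect_error(read_volume(path), "space directions")
  unlink(path)
  expect_error(voxel_image(array(0, c(2, 2, 2)), spacing = c(1, 0, 1)),
               "spacing")
})

test_that("fixed-bin-width discretisation follows the floor rule", {
  d <- discretize_fixed_bin_width(c(0, 24, 25, 49, 100), 25)
  expect_identical(d$levels, c(1L, 1L, 2L, 2L, 5L))
  expect_identical(d$Ng, 5L)
  dc <- discretize_fixed_bin_width(rep(7.5, 10), 25)
  expect_true(all(dc$levels == 1L))
  expect_identical(dc$Ng, 1L)
  set.seed(3)
  x <- rnorm(500, 0, 40)
  expect_gte(discretize_fixed_bin_width(x, 10)$Ng,
             discretize_fixed_bin_width(x, 100)$Ng)
  # translation covariance
  expect_identical(discretize_fixed_bin_width(x, 25)$levels,
                   discretize_fixed_bin_width(x + 1234.5, 25)$levels)
  expect_error(discretize_fixed_bin_width(numeric(0), 25), "empty")
  expect_error(discretize_fixed_bin_width(c(1, NA), 25), "finite")
})

test_that("spherical masks hit the requested volume", {
  g <- grid_spec(c(48, 48, 48), 0.26)
  m <- make_spherical_mask(g, c(0, 0, 0), 92.24)
  expect_lt(abs(mask_volume(m) - 92.24) / 92.24, 0.05)
  # volume below the voxel resolution
  gc <- grid_spec(c(8, 8, 8), 2)
  expect_error(make_spherical_mask(gc, c(0, 0, 0), 0.05), "resolution")
  # voxelised volume converges towards 4/3 pi r^3 with finer spacing
  v <- 4 / 3 * pi * 2^3
  e1 <- abs(mask_volume(make_spherical_mask(grid_spec(c(24, 24, 24), 0.5),
                                            c(0, 0, 0), v)) - v) / v
  e2 <- abs(mask_volume(make_spherical_mask(grid_spec(c(96, 96, 96), 0.125),
                                            c(0, 0, 0), v)) - v) / v
  expect_lt(e2, e1)
  expect_lt(e2, 0.01)
})

test_that("sphere rasterisation matches brute-force centre enumeration", {
  # r ~ 2.1 voxel units on unit spacing (off a lattice-distance boundary)
  g <- grid_spec(c(9, 9, 9), 1)
  v <- 4 / 3 * pi * 2.1^3
  m <- make_spherical_mask(g, c(0, 0, 0), v)
  r <- (3 * v / (4 * pi))^(1 / 3)
  cnt <- 0L
  for (i in -4:4) for (j in -4:4) for (k in -4:4)
    if (i^2 + j^2 + k^2 <= r^2) cnt <- cnt + 1L
  expect_identical(mask_voxel_count(m), cnt)
})

test_that("slice-thickness resampling changes only the slice axis", {
  set.seed(4)
  g <- grid_spec(c(16, 16, 20), 0.26)
  img <- voxel_image(array(rnorm(16 * 16 * 20, 500, 30), c(16, 16, 20)),
                     spacing = 0.26, origin = g$origin)
  # identity
  same <- resample_slice_thickness(img, 0.26)
  expect_identical(same$values, img$values)
  # constant image stays constant at any thickness
  cimg <- voxel_image(array(7, c(16, 16, 20)), spacing = 0.26)
  rc <- resample_slice_thickness(cimg, 0.5)
  expect_true(all(abs(rc$values - 7) < 1e-12))
  expect_equal(rc$spacing, c(0.26, 0.26, 0.5))
  # slice count follows round(extent / new_thickness)
  r <- resample_slice_thickness(img, 0.5)
  expect_identical(dim(r$values)[3], as.integer(round(20 * 0.26 / 0.5)))
  expect_identical(dim(r$values)[1:2], dim(img$values)[1:2])
  # mask resampling preserves binarity
  msk <- make_spherical_mask(g, c(0, 0, 0), 5)
  rm_ <- resample_slice_thickness(img, 0.2, msk)
  expect_true(all(rm_$mask$values %in% c(0L, 1L)))
  expect_error(resample_slice_thickness(img, -1), "new_thickness")
})
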