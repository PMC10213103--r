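test_that("first-order features match direct formulas and the oracle", {
  d <- discretize_fixed_bin_width(c(1, 2, 3, 4), 1)
  f <- compute_first_order(c(1, 2, 3, 4), d, voxel_volume = 1)
  expect_equal(unname(f["Mean"]), 2.5)
  expect_equal(unname(f["Range"]), 3)
  expect_equal(unname(f["Median"]), 2.5)
  # constant ROI degenerates cleanly
  dc <- discretize_fixed_bin_width(rep(5, 20), 25)
  fc <- compute_first_order(rep(5, 20), dc, 0.1)
  expect_equal(unname(fc[c("Variance", "Entropy")]), c(0, 0))
  expect_equal(unname(fc["Uniformity"]), 1)
  # random ROI against the naive re-implementation
  set.seed(10)
  x <- rnorm(200, 900, 120)
  dr <- discretize_fixed_bin_width(x, 25)
  got <- compute_first_order(x, dr, voxel_volume = 0.26^3)
  want <- oracle_first_order(x, dr$levels, dr$Ng, 0.26^3)
  expect_equal(got[names(want)], want, tolerance = 1e-10)
})

test_that("shape features recover analytic sphere geometry", {
  # digitised ball at 0.1 mm spacing: mesh volume within 2% of 4/3 pi r^3
  r <- 2
  g <- grid_spec(c(45, 45, 45), 0.1)
  m <- make_spherical_mask(g, c(0, 0, 0), 4 / 3 * pi * r^3)
  f <- compute_shape(m)
  vol <- 4 / 3 * pi * r^3
  expect_lt(abs(f[["MeshVolume"]] - vol) / vol, 0.02)
  expect_lte(f[["Sphericity"]], 1)
  # sphericity approaches 1 from below as sampling refines
  g2 <- grid_spec(c(23, 23, 23), 0.2)
  f2 <- compute_shape(make_spherical_mask(g2, c(0, 0, 0), vol))
  expect_gt(f[["Sphericity"]], f2[["Sphericity"]])
  expect_gt(f[["Sphericity"]], 0.97)
  # axis lengths of a ball are all 2r-ish and isotropic
  expect_lt(abs(f[["Elongation"]] - 1), 0.02)
  expect_lt(abs(f[["Flatness"]] - 1), 0.02)
})

test_that("shape handles cubes, anisotropy and degenerate masks", {
  cube <- roi_mask(array(1L, c(3, 3, 3)), spacing = 1)
  f <- compute_shape(cube)
  expect_equal(f[["VoxelVolume"]], 27)
  expect_equal(f[["Maximum3DDiameter"]], 2 * sqrt(3), tolerance = 1e-12)
  expect_equal(f[["Maximum2DDiameterSlice"]], 2 * sqrt(2), tolerance = 1e-12)
  expect_true(f[["MeshVolume"]] > 8 && f[["MeshVolume"]] < 27)
  expect_lte(f[["Sphericity"]], 1)
  # single voxel: voxel volume defined, mesh features NA by policy
  single <- roi_mask(array(c(1L, rep(0L, 7)), c(2, 2, 2)),
                     spacing = c(0.5, 0.5, 1))
  expect_warning(fs <- compute_shape(single), "single-voxel")
  expect_equal(fs[["VoxelVolume"]], 0.25)
  expect_true(is.na(fs[["MeshVolume"]]))
  # shape is invariant to intensity content by construction: it only sees
  # the mask; anisotropic spacing enters the physical axes
  aniso <- roi_mask(array(1L, c(4, 4, 2)), spacing = c(1, 1, 3))
  fa <- compute_shape(aniso)
  expect_equal(fa[["VoxelVolume"]], 4 * 4 * 2 * 3)
})

test_that("wavelet decomposition yields 8 same-geometry bands", {
  set.seed(11)
  img <- voxel_image(array(rnorm(10 * 12 * 8), c(10, 12, 8)),
                     spacing = c(0.3, 0.3, 0.5))
  bands <- wavelet_decompose(img)
  expect_named(bands, c("LLL", "LLH", "LHL", "LHH",
                        "HLL", "HLH", "HHL", "HHH"))
  for (b in bands) {
    expect_identical(dim(b$values), dim(img$values))
    expect_equal(b$spacing, img$spacing)
  }
  zero <- voxel_image(array(0, c(6, 6, 6)), spacing = 1)
  zb <- wavelet_decompose(zero)
  expect_true(all(vapply(zb, function(b) all(b$values == 0), TRUE)))
  expect_error(wavelet_decompose(voxel_image(array(0, c(1, 4, 4)),
                                             spacing = 1)),
               "at least 2")
})

make_fixture <- function(seed = 21, n = 20L) {
  set.seed(seed)
  g <- grid_spec(c(n, n, n), 1)
  img <- voxel_image(array(rnorm(n^3, 100, 15), rep(n, 3)), spacing = 1,
                     origin = g$origin)
  list(img = img, msk = make_spherical_mask(g, c(0, 0, 0), 250), g = g)
}

test_that("default extraction yields the full 842-feature inventory", {
  fx <- make_fixture()
  fv <- extract_all(fx$img, fx$msk, extraction_config(slice_thickness = NULL))
  expect_length(fv, 842L)
  expect_false(anyDuplicated(names(fv)) > 0)
  expect_true(all(is.finite(fv[!startsWith(names(fv), "original_shape")])))
  # shape off removes exactly the 14 shape features
  fv2 <- extract_all(fx$img, fx$msk,
                     extraction_config(slice_thickness = NULL, shape = FALSE))
  expect_length(fv2, 842L - 14L)
  # wavelet off leaves the 106 original features
  fv3 <- extract_all(fx$img, fx$msk,
                     extraction_config(slice_thickness = NULL,
                                       wavelet = FALSE))
  expect_length(fv3, 106L)
  # determinism
  fv4 <- extract_all(fx$img, fx$msk, extraction_config(slice_thickness = NULL))
  expect_identical(fv, fv4)
})

test_that("intensity features are translation-covariant and mask-invariant", {
  fx <- make_fixture(31)
  cfg <- extraction_config(slice_thickness = NULL, wavelet = FALSE,
                           shape = FALSE)
  fv <- extract_all(fx$img, fx$msk, cfg)
  shifted <- voxel_image(fx$img$values + 500, spacing = fx$img$spacing,
                         origin = fx$img$origin)
  fvs <- extract_all(shifted, fx$msk, cfg)
  # all discretisation-based features unchanged by an intensity offset
  loc_dep <- grep("firstorder", names(fv))
  expect_equal(fv[-loc_dep], fvs[-loc_dep], tolerance = 1e-9)
  # intensity features invariant to mask translation on a homogeneous image
  hom <- voxel_image(array(42, dim(fx$img$values)),
                     spacing = fx$img$spacing, origin = fx$img$origin)
  m1 <- make_spherical_mask(fx$g, c(-3, 0, 0), 100)
  m2 <- make_spherical_mask(fx$g, c(3, 2, 1), 100)
  expect_equal(extract_all(hom, m1, cfg), extract_all(hom, m2, cfg),
               tolerance = 1e-12)
})

test_that("misaligned grids and empty masks are rejected", {
  fx <- make_fixture()
  bad <- roi_mask(array(0L, c(4, 4, 4)), spacing = 1)
  expect_error(extract_all(fx$img, bad), "shape")
  empty <- roi_mask(array(0L, dim(fx$img$values)), spacing = 1,
                    origin = fx$img$origin)
  expect_error(extract_all(fx$img, empty), "empty")
})
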