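#' Feature-extraction configuration
#'
#' Bundles the preprocessing and extraction settings swept in the
#' repeatability studies. The defaults are the recommended workflow settings
#' (bin width 25, slice thickness 0.26 mm, wavelet filtering on), under which
#' a full extraction yields exactly 842 features: 106 on the original image
#' (shape 14, first order 18, GLCM 23, GLRLM 16, GLSZM 16, GLDM 14, NGTDM 5)
#' plus the 6 non-shape classes (92 features) on each of 8 wavelet bands.
#'
#' @param bin_width fixed bin width in scanner units (> 0); the study grid is
#'   10, 25, 50, 100.
#' @param slice_thickness resampled slice spacing in mm (study grid 0.2,
#'   0.26, 0.3, 0.5, 1.0), or `NULL` to keep the native spacing.
#' @param wavelet extract wavelet-filtered variants of the intensity classes.
#' @param shape extract shape features.
#' @param distance GLCM co-occurrence distance in voxels (>= 1).
#' @param gldm_alpha GLDM dependence tolerance in gray levels.
#' @return An object of class `extraction_config`.
#' @export
extraction_config <- function(bin_width = 25, slice_thickness = 0.26,
                              wavelet = TRUE, shape = TRUE,
                              distance = 1L, gldm_alpha = 0) {
  if (!is.finite(bin_width) || bin_width <= 0)
    stop("extraction_config: bin_width must be > 0")
  if (!is.null(slice_thickness) &&
      (!is.finite(slice_thickness) || slice_thickness <= 0))
    stop("extraction_config: slice_thickness must be > 0 or NULL")
  if (distance < 1) stop("extraction_config: distance must be >= 1")
  structure(list(bin_width = bin_width, slice_thickness = slice_thickness,
                 wavelet = isTRUE(wavelet), shape = isTRUE(shape),
                 distance = as.integer(distance), gldm_alpha = gldm_alpha),
            class = "extraction_config")
}

intensity_classes <- c("firstorder", "glcm", "glrlm", "glszm", "gldm",
                       "ngtdm")

# features of the six intensity classes for one (image values, mask) pair
extract_intensity_classes <- function(values, maskvals, voxel_volume,
                                      config) {
  cropped <- crop_to_roi(values, maskvals)
  ints <- cropped$values[cropped$inroi]
  disc <- discretize_fixed_bin_width(ints, config$bin_width)
  lv <- level_array(disc, cropped$inroi)
  n <- length(ints)
  c(
    prefix_names(compute_first_order(ints, disc, voxel_volume), "firstorder"),
    prefix_names(compute_glcm_features(lv, disc$Ng, config$distance), "glcm"),
    prefix_names(compute_glrlm_features(lv, disc$Ng, n), "glrlm"),
    prefix_names(compute_glszm_features(lv, disc$Ng, n), "glszm"),
    prefix_names(compute_gldm_features(lv, disc$Ng, config$gldm_alpha),
                 "gldm"),
    prefix_names(compute_ngtdm_features(lv, disc$Ng), "ngtdm")
  )
}

prefix_names <- function(x, class, filter = NULL) {
  names(x) <- if (is.null(filter)) paste0(class, "_", names(x))
              else paste0(filter, "_", class, "_", names(x))
  x
}

#' Extract the full radiomic feature vector
#'
#' Runs the complete pipeline on one image/mask pair: optional
#' slice-thickness resampling, shape features on the mask, fixed-bin-width
#' discretisation and the five texture families on the original image, and
#' (when enabled) the six intensity classes on each of the eight wavelet
#' sub-bands. Deterministic: identical inputs give identical vectors.
#'
#' @param image a [voxel_image()].
#' @param mask an [roi_mask()] aligned to `image` with at least one voxel.
#' @param config an [extraction_config()].
#' @return Named numeric vector; names follow
#'   `<filter>_<class>_<feature>` with filter `original` or `wavelet-LLL` ..
#'   `wavelet-HHH`. 842 entries under the defaults.
#' @examples
#' g <- grid_spec(c(24, 24, 24), 1)
#' img <- voxel_image(array(stats::rnorm(24^3, 100, 10), c(24, 24, 24)),
#'                    spacing = 1, origin = g$origin)
#' msk <- make_spherical_mask(g, c(0, 0, 0), 300)
#' fv <- extract_all(img, msk, extraction_config(slice_thickness = NULL))
#' length(fv)  # 842
#' @export
extract_all <- function(image, mask, config = extraction_config()) {
  extract_multi(image, list(mask), config)[[1]]
}

#' Extract features for several ROIs on one image
#'
#' Shares the expensive per-image work (resampling, wavelet decomposition)
#' across masks; equivalent to calling [extract_all()] per mask.
#'
#' @param image a [voxel_image()].
#' @param masks list of [roi_mask()]s aligned to `image`.
#' @param config an [extraction_config()].
#' @return List of named feature vectors, one per mask.
#' @export
extract_multi <- function(image, masks, config = extraction_config()) {
  stopifnot(inherits(image, "voxel_image"), length(masks) >= 1L)
  stopifnot(inherits(config, "extraction_config"))
  for (m in masks) {
    check_aligned(image, m)
    if (mask_voxel_count(m) < 1L) stop("extract: empty mask")
  }
  if (!is.null(config$slice_thickness) &&
      abs(config$slice_thickness - image$spacing[3]) > 1e-12) {
    res <- lapply(masks, function(m)
      resample_slice_thickness(image, config$slice_thickness, m)$mask)
    image <- resample_slice_thickness(image, config$slice_thickness)
    masks <- res
  }
  voxvol <- prod(image$spacing)
  bands <- if (config$wavelet) wavelet_decompose(image) else NULL
  lapply(masks, function(mask) {
    if (mask_voxel_count(mask) < 1L)
      stop("extract: mask became empty after resampling")
    fv <- numeric(0)
    if (config$shape)
      fv <- c(fv, prefix_names(compute_shape(mask), "shape", "original"))
    orig <- extract_intensity_classes(image$values, mask$values, voxvol,
                                      config)
    fv <- c(fv, stats::setNames(orig, paste0("original_", names(orig))))
    if (config$wavelet) {
      for (nm in names(bands)) {
        bf <- extract_intensity_classes(bands[[nm]]$values, mask$values,
                                        voxvol, config)
        fv <- c(fv, stats::setNames(bf, paste0("wavelet-", nm, "_",
                                               names(bf))))
      }
    }
    fv
  })
}
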