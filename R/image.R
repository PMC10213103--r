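#' Voxel grid geometry
#'
#' A `grid_spec` describes a regular 3-D voxel lattice: the number of voxels
#' per axis, the physical spacing between voxel centres (mm), and the physical
#' position of the first voxel centre (mm). Axis 3 is the slice direction.
#'
#' @param shape integer vector of length 3, voxels per axis (all >= 1).
#' @param spacing numeric vector of length 3, mm per voxel along each axis
#'   (all > 0). A scalar is recycled to an isotropic grid.
#' @param origin numeric vector of length 3, mm position of the first voxel
#'   centre. Defaults to the grid centred on the physical origin.
#' @return An object of class `grid_spec`.
#' @examples
#' grid_spec(c(64, 64, 64), 0.26)
#' @export
grid_spec <- function(shape, spacing = 0.26, origin = NULL) {
  shape <- as.integer(rep_len(shape, 3L))
  spacing <- as.numeric(rep_len(spacing, 3L))
  if (any(shape < 1L)) stop("grid_spec: all shape entries must be >= 1")
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("grid_spec: all spacings must be positive and finite")
  if (is.null(origin)) origin <- -(shape - 1) * spacing / 2
  origin <- as.numeric(rep_len(origin, 3L))
  if (any(!is.finite(origin))) stop("grid_spec: origin must be finite")
  structure(list(shape = shape, spacing = spacing, origin = origin),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("grid_spec: %s voxels, spacing %s mm, origin %s mm\n",
              paste(x$shape, collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x"),
              paste(signif(x$origin, 4), collapse = ", ")))
  invisible(x)
}

#' 3-D scalar volume with physical geometry
#'
#' The basic scan container: a 3-D numeric array of scanner-unit intensities
#' plus per-axis voxel spacing (mm) and the position of the first voxel
#' centre (mm).
#'
#' @param values 3-D numeric array of finite intensities.
#' @param spacing numeric length-3 (or scalar) voxel spacing in mm, all > 0.
#' @param origin numeric length-3 position (mm) of the first voxel centre.
#' @return An object of class `voxel_image` with fields `values`, `spacing`,
#'   `origin`.
#' @seealso [roi_mask()], [read_volume()], [write_volume()]
#' @export
voxel_image <- function(values, spacing = 0.26, origin = c(0, 0, 0)) {
  values <- as.array(values)
  if (length(dim(values)) != 3L)
    stop("voxel_image: values must be a 3-D array")
  if (!all(is.finite(values)))
    stop("voxel_image: all intensities must be finite")
  spacing <- as.numeric(rep_len(spacing, 3L))
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("voxel_image: spacing must be positive along every axis")
  origin <- as.numeric(rep_len(origin, 3L))
  structure(list(values = values, spacing = spacing, origin = origin),
            class = "voxel_image")
}

#' @export
print.voxel_image <- function(x, ...) {
  v <- x$values
  cat(sprintf(
    "voxel_image: %s voxels, spacing %s mm, intensity range [%.4g, %.4g]\n",
    paste(dim(v), collapse = "x"),
    paste(signif(x$spacing, 4), collapse = "x"), min(v), max(v)))
  invisible(x)
}

#' Binary region-of-interest mask
#'
#' A segmentation aligned to a [voxel_image()]: same array shape, same
#' spacing, same origin; voxel values are 0 (outside) or 1 (inside).
#'
#' @param values 3-D array coercible to 0/1 (logical arrays accepted).
#' @param spacing,origin geometry, as for [voxel_image()].
#' @return An object of class `roi_mask`.
#' @export
roi_mask <- function(values, spacing = 0.26, origin = c(0, 0, 0)) {
  values <- as.array(values)
  if (length(dim(values)) != 3L) stop("roi_mask: values must be a 3-D array")
  if (is.logical(values)) values <- values * 1L
  if (!all(values %in% c(0, 1)))
    stop("roi_mask: mask values must be binary (0/1)")
  spacing <- as.numeric(rep_len(spacing, 3L))
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("roi_mask: spacing must be positive along every axis")
  origin <- as.numeric(rep_len(origin, 3L))
  structure(list(values = array(as.integer(values), dim(values)),
                 spacing = spacing, origin = origin),
            class = "roi_mask")
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("roi_mask: %s voxels, %d in ROI (%.3g mm^3)\n",
              paste(dim(x$values), collapse = "x"), sum(x$values),
              sum(x$values) * prod(x$spacing)))
  invisible(x)
}

#' Number of voxels inside a mask
#' @param mask an [roi_mask()].
#' @return Integer voxel count.
#' @export
mask_voxel_count <- function(mask) sum(mask$values)

#' Physical volume of a mask in cubic millimetres
#' @param mask an [roi_mask()].
#' @return Voxel count times voxel volume (mm^3).
#' @export
mask_volume <- function(mask) sum(mask$values) * prod(mask$spacing)

# internal: check image/mask alignment (shape + spacing; origin to 1e-6 mm)
check_aligned <- function(image, mask) {
  if (!identical(dim(image$values), dim(mask$values)))
    stop("image and mask have different array shapes")
  if (any(abs(image$spacing - mask$spacing) > 1e-9))
    stop("image and mask have different voxel spacings")
  if (any(abs(image$origin - mask$origin) > 1e-6))
    stop("image and mask have different origins")
  invisible(TRUE)
}
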