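#' Fixed-bin-width intensity discretisation
#'
#' Maps raw region-of-interest intensities to integer gray levels using bins
#' of constant width anchored at the ROI minimum:
#' `level(x) = floor((x - min) / bin_width) + 1`. The ROI maximum falls in its
#' own top bin, so `Ng = level(max)`. All texture matrices operate on these
#' levels, which makes them invariant to adding a constant to the raw
#' intensities.
#'
#' @param intensities numeric vector of ROI voxel intensities (scanner units).
#' @param bin_width positive bin width in scanner units (default 25).
#' @return An object of class `discretized_roi` with fields `levels` (integer
#'   vector, values in `1..Ng`), `Ng`, `bin_width`, `roi_min`.
#' @examples
#' discretize_fixed_bin_width(c(0, 24, 25, 49, 100), 25)$levels
#' @export
discretize_fixed_bin_width <- function(intensities, bin_width = 25) {
  if (length(intensities) < 1L)
    stop("discretize_fixed_bin_width: empty ROI")
  if (!all(is.finite(intensities)))
    stop("discretize_fixed_bin_width: non-finite intensities")
  if (!is.finite(bin_width) || bin_width <= 0)
    stop("discretize_fixed_bin_width: bin_width must be > 0")
  roi_min <- min(intensities)
  levels <- as.integer(floor((intensities - roi_min) / bin_width)) + 1L
  structure(list(levels = levels, Ng = max(levels),
                 bin_width = bin_width, roi_min = roi_min),
            class = "discretized_roi")
}

#' Rasterise a sphere of given physical volume
#'
#' The sphere radius is derived from the requested volume,
#' `r = (3V / 4 pi)^(1/3)`; a voxel belongs to the mask iff its centre lies
#' within `r` of the sphere centre. The achieved voxelised volume differs from
#' the request by a discretisation error that shrinks with spacing (about 5%
#' at 0.26 mm for the ~92 mm^3 segmentations used here).
#'
#' @param grid a [grid_spec()].
#' @param centre sphere centre in physical mm coordinates (length 3).
#' @param volume target sphere volume in mm^3 (> 0).
#' @return An [roi_mask()] on the grid.
#' @examples
#' g <- grid_spec(c(48, 48, 48), 0.26)
#' m <- make_spherical_mask(g, c(0, 0, 0), 92.24)
#' mask_volume(m)  # close to 92.24
#' @export
make_spherical_mask <- function(grid, centre = NULL, volume) {
  stopifnot(inherits(grid, "grid_spec"))
  if (!is.finite(volume) || volume <= 0)
    stop("make_spherical_mask: volume must be > 0")
  if (is.null(centre))
    centre <- grid$origin + (grid$shape - 1) * grid$spacing / 2
  centre <- as.numeric(rep_len(centre, 3L))
  r <- (3 * volume / (4 * pi))^(1 / 3)
  ax <- lapply(1:3, function(a)
    grid$origin[a] + (seq_len(grid$shape[a]) - 1) * grid$spacing[a] - centre[a])
  d2 <- outer(outer(ax[[1]]^2, ax[[2]]^2, `+`), ax[[3]]^2, `+`)
  inside <- d2 <= r^2
  if (!any(inside))
    stop(sprintf(paste0(
      "make_spherical_mask: no voxel centre falls inside the sphere; ",
      "volume %.3g mm^3 is below the resolution limit (voxel volume ",
      "%.3g mm^3) - use a volume of at least a few voxels"),
      volume, prod(grid$spacing)))
  roi_mask(inside, spacing = grid$spacing, origin = grid$origin)
}

#' Resample the slice direction of a volume
#'
#' Changes only the slice-direction (axis 3) spacing; in-plane spacing is
#' untouched. The image is interpolated linearly along the slice axis and an
#' optional mask with nearest-neighbour interpolation, so masks stay binary.
#' The resampled grid covers the same physical extent to within one voxel:
#' the new slice count is `round(extent / new_thickness)` where
#' `extent = n_slices * old_thickness`.
#'
#' @param image a [voxel_image()].
#' @param new_thickness new slice spacing in mm (> 0).
#' @param mask optional [roi_mask()] aligned to `image`, resampled alongside.
#' @return A `voxel_image`, or `list(image=, mask=)` when a mask is supplied.
#' @export
resample_slice_thickness <- function(image, new_thickness, mask = NULL) {
  stopifnot(inherits(image, "voxel_image"))
  if (!is.finite(new_thickness) || new_thickness <= 0)
    stop("resample_slice_thickness: new_thickness must be > 0")
  if (!is.null(mask)) check_aligned(image, mask)
  old <- image$spacing[3]
  nz <- dim(image$values)[3]
  if (abs(new_thickness - old) < 1e-12) {
    return(if (is.null(mask)) image else list(image = image, mask = mask))
  }
  extent <- nz * old
  nz_new <- max(1L, as.integer(round(extent / new_thickness)))
  # new voxel-centre positions expressed in old fractional slice index
  zpos <- (seq_len(nz_new) - 1) * new_thickness / old
  i0 <- pmin.int(pmax.int(floor(zpos), 0), nz - 1)
  i1 <- pmin.int(i0 + 1, nz - 1)
  w <- pmin(pmax(zpos - i0, 0), 1)
  interp_axis3 <- function(arr, nearest) {
    d <- dim(arr)
    m <- matrix(arr, nrow = d[1] * d[2], ncol = d[3])
    out <- if (nearest) {
      m[, ifelse(w < 0.5, i0, i1) + 1, drop = FALSE]
    } else {
      m[, i0 + 1, drop = FALSE] * rep(1 - w, each = nrow(m)) +
        m[, i1 + 1, drop = FALSE] * rep(w, each = nrow(m))
    }
    array(out, c(d[1], d[2], nz_new))
  }
  spacing_new <- c(image$spacing[1:2], new_thickness)
  img_out <- voxel_image(interp_axis3(image$values, nearest = FALSE),
                         spacing = spacing_new, origin = image$origin)
  if (is.null(mask)) return(img_out)
  msk_out <- roi_mask(interp_axis3(mask$values, nearest = TRUE),
                      spacing = spacing_new, origin = mask$origin)
  list(image = img_out, mask = msk_out)
}
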