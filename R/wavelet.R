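# Coiflet-1 analysis filters (low/high pass, quadrature mirror pair).
coif1_lo <- c(-0.015655728135465,
              -0.072732619512854,
               0.384864846864203,
               0.852572020212255,
               0.337897662457809,
              -0.072732619512854)
coif1_hi <- rev(coif1_lo) * rep(c(-1, 1), 3)

#' Single-level 3-D wavelet decomposition (8 sub-bands)
#'
#' Applies the Coiflet-1 low (L) or high (H) pass analysis filter along each
#' axis in turn, undecimated with symmetric boundary padding, giving the
#' eight sub-band images LLL, LLH, LHL, LHH, HLL, HLH, HHL, HHH (letter k is
#' the filter on axis k). Every band keeps the input shape, spacing and
#' origin, so ROI masks defined on the input apply unchanged.
#'
#' @param image a [voxel_image()] with at least 2 voxels per axis.
#' @return Named list of 8 [voxel_image()] sub-bands.
#' @export
wavelet_decompose <- function(image) {
  stopifnot(inherits(image, "voxel_image"))
  if (any(dim(image$values) < 2L))
    stop("wavelet_decompose: image must have at least 2 voxels per axis")
  bands <- list(`1` = image$values)
  for (axis in 1:3) {
    nxt <- list()
    for (nm in names(bands)) {
      arr <- bands[[nm]]
      nxt[[paste0(nm, "L")]] <- conv_axis(arr, coif1_lo, axis)
      nxt[[paste0(nm, "H")]] <- conv_axis(arr, coif1_hi, axis)
    }
    bands <- nxt
  }
  names(bands) <- sub("^1", "", names(bands))
  order_names <- c("LLL", "LLH", "LHL", "LHH", "HLL", "HLH", "HHL", "HHH")
  bands <- bands[order_names]
  lapply(bands, function(v)
    voxel_image(v, spacing = image$spacing, origin = image$origin))
}
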