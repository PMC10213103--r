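#' First-order intensity statistics (18 features)
#'
#' Computes the standard first-order radiomics set from the raw ROI
#' intensities, with Entropy and Uniformity taken over the fixed-bin-width
#' gray-level histogram of `disc`. Percentiles use linear interpolation.
#' Skewness and Kurtosis use population moments (Kurtosis is not
#' excess-corrected); a constant ROI returns 0 for both by the package's
#' degenerate-value policy.
#'
#' @param intensities numeric vector of raw ROI intensities.
#' @param disc a [discretize_fixed_bin_width()] result for the same ROI.
#' @param voxel_volume physical volume of one voxel in mm^3.
#' @return Named numeric vector of 18 features (unprefixed names,
#'   e.g. `Mean`, `10Percentile`).
#' @export
compute_first_order <- function(intensities, disc, voxel_volume = 1) {
  x <- as.numeric(intensities)
  n <- length(x)
  if (n < 1L) stop("compute_first_order: empty ROI")
  p <- tabulate(disc$levels, nbins = disc$Ng) / n
  p <- p[p > 0]
  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  m3 <- mean((x - mu)^3)
  m4 <- mean((x - mu)^4)
  q <- stats::quantile(x, c(0.10, 0.25, 0.50, 0.75, 0.90), names = FALSE)
  sub <- x[x >= q[1] & x <= q[5]]
  c(
    Energy = sum(x^2),
    TotalEnergy = voxel_volume * sum(x^2),
    Entropy = -sum(p * log2(p)),
    Minimum = min(x),
    `10Percentile` = q[1],
    `90Percentile` = q[5],
    Maximum = max(x),
    Mean = mu,
    Median = q[3],
    InterquartileRange = q[4] - q[2],
    Range = max(x) - min(x),
    MeanAbsoluteDeviation = mean(abs(x - mu)),
    RobustMeanAbsoluteDeviation =
      if (length(sub)) mean(abs(sub - mean(sub))) else 0,
    RootMeanSquared = sqrt(mean(x^2)),
    Skewness = if (m2 > 0) m3 / m2^1.5 else 0,
    Kurtosis = if (m2 > 0) m4 / m2^2 else 0,
    Variance = m2,
    Uniformity = sum(p^2)
  )
}
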