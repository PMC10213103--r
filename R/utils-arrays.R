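# Array utilities shared by the texture-matrix builders, the wavelet
# transform and the phantom noise fields. All operate on plain 3-D arrays.

# The 13 unique 3-D lattice directions (one per +/- pair) at distance-1
# chebyshev offsets; together with their negatives they give the full
# 26-neighbourhood.
directions13 <- function() {
  dirs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  dirs <- dirs[!(dirs[, 1] == 0 & dirs[, 2] == 0 & dirs[, 3] == 0), ]
  # keep one of each +/- pair: first nonzero component positive
  keep <- apply(dirs, 1, function(d) d[match(TRUE, d != 0)] > 0)
  unname(dirs[keep, , drop = FALSE])
}

directions26 <- function() {
  d <- directions13()
  rbind(d, -d)
}

# Shift a 3-D array by an integer offset, filling exposed entries with `fill`.
# out[i,j,k] = arr[i+d1, j+d2, k+d3] where defined.
shift_array <- function(arr, d, fill = NA) {
  dm <- dim(arr)
  src <- vector("list", 3L)
  dst <- vector("list", 3L)
  for (a in 1:3) {
    n <- dm[a]
    off <- d[a]
    if (off >= 0) {
      src[[a]] <- seq_len(n - off) + off
      dst[[a]] <- seq_len(n - off)
    } else {
      src[[a]] <- seq_len(n + off)
      dst[[a]] <- seq_len(n + off) - off
    }
    if (length(src[[a]]) == 0L) return(array(fill, dm))
  }
  out <- array(fill, dm)
  out[dst[[1]], dst[[2]], dst[[3]]] <- arr[src[[1]], src[[2]], src[[3]]]
  out
}

# Reflect an out-of-range index into 1..n (half-sample symmetric padding).
reflect_index <- function(idx, n) {
  if (n == 1L) return(rep(1L, length(idx)))
  period <- 2L * n
  idx <- (idx - 1L) %% period
  idx <- ifelse(idx < 0L, idx + period, idx)
  as.integer(ifelse(idx < n, idx + 1L, period - idx))
}

# 1-D convolution of a 3-D array along one axis with symmetric padding.
# Kernel offsets are centred: offset k applies to index i + k - centre.
conv_axis <- function(arr, kernel, axis, centre = (length(kernel) + 1) %/% 2) {
  dm <- dim(arr)
  perm <- c(axis, setdiff(1:3, axis))
  x <- aperm(arr, perm)
  n <- dim(x)[1]
  m <- matrix(x, nrow = n)
  out <- matrix(0, nrow = n, ncol = ncol(m))
  base <- seq_len(n)
  for (k in seq_along(kernel)) {
    idx <- reflect_index(base + (k - centre), n)
    out <- out + kernel[k] * m[idx, , drop = FALSE]
  }
  res <- array(out, dim(x))
  aperm(res, order(perm))
}

# Separable Gaussian smoothing with per-axis sigma in voxels (0 = no-op).
gaussian_smooth <- function(arr, sigma) {
  sigma <- rep_len(sigma, 3L)
  for (a in 1:3) {
    s <- sigma[a]
    if (s <= 0) next
    r <- max(1L, ceiling(3 * s))
    k <- exp(-0.5 * ((-r):r / s)^2)
    k <- k / sum(k)
    arr <- conv_axis(arr, k, a, centre = r + 1L)
  }
  arr
}

# Crop image values and mask to the mask bounding box; returns the cropped
# value array with NA outside the ROI plus the logical in-ROI array.
crop_to_roi <- function(values, mask_values) {
  idx <- which(mask_values != 0, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("empty ROI")
  rng <- apply(idx, 2, range)
  sub <- values[rng[1, 1]:rng[2, 1], rng[1, 2]:rng[2, 2],
                rng[1, 3]:rng[2, 3], drop = FALSE]
  msk <- mask_values[rng[1, 1]:rng[2, 1], rng[1, 2]:rng[2, 2],
                     rng[1, 3]:rng[2, 3], drop = FALSE] != 0
  sub <- array(sub, dim(msk))
  sub[!msk] <- NA_real_
  list(values = sub, inroi = msk)
}

# Build the level array (NA outside ROI) for texture-matrix construction
# from a discretized_roi and the logical in-ROI array it came from.
level_array <- function(disc, inroi) {
  lv <- array(NA_real_, dim(inroi))
  lv[inroi] <- disc$levels
  lv
}
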