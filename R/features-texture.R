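# Texture-matrix feature families. All operate on a "level array": the ROI
# bounding box with integer gray levels inside the ROI and NA outside
# (see level_array()). Levels come from fixed-bin-width discretisation, so
# every family is invariant to adding a constant to the raw intensities.
#
# GLCM and GLRLM are accumulated per lattice direction (13 unique 3-D
# directions at chebyshev distance 1) and the feature values averaged over
# directions. GLSZM/GLDM/NGTDM use the full 26-neighbourhood.
#
# Degenerate single-level regions return documented sentinel values (0) for
# features whose definitions divide by zero (Correlation, Imc1, Imc2, MCC,
# Busyness, InverseVariance, ...); NGTDM Coarseness is capped at 1e6.

COARSENESS_CAP <- 1e6

# sum `w` within integer groups 1..n
group_sum <- function(w, g, n) {
  out <- numeric(n)
  rs <- rowsum(w, g)
  out[as.integer(rownames(rs))] <- rs[, 1]
  out
}

#' Gray-level co-occurrence features (23 features)
#'
#' Builds one symmetric normalised co-occurrence matrix per 3-D direction at
#' the given voxel distance and averages each feature over the 13 unique
#' directions.
#'
#' @param lv level array (`NA` outside the ROI), from [level_array()].
#' @param Ng number of gray levels.
#' @param distance co-occurrence offset in voxels (default 1).
#' @return Named numeric vector of 23 features.
#' @export
compute_glcm_features <- function(lv, Ng, distance = 1L) {
  dirs <- directions13() * as.integer(distance)
  acc <- NULL
  for (r in seq_len(nrow(dirs))) {
    f <- glcm_features_dir(lv, Ng, dirs[r, ])
    acc <- if (is.null(acc)) f else acc + f
  }
  acc / nrow(dirs)
}

# Features of the symmetric normalised co-occurrence matrix for one
# direction, computed from the symmetrised pair list. Most features depend
# only on the marginal (px), difference (p_{x-y}) and sum (p_{x+y})
# distributions; the exact identities used are
#   sum_ij i*j*P   = (sum_s s^2 p_s - sum_k k^2 p_d) / 4,
#   HXY1 = HXY2 = HX + HY (product of the marginals),
# and for MCC, Q = A^2 with A the row-stochastic D^-1 P, so Q's eigenvalues
# are the squares of those of the symmetric D^-1/2 P D^-1/2.
glcm_features_dir <- function(lv, Ng, d) {
  b <- shift_array(lv, d)
  ok <- !is.na(lv) & !is.na(b)
  a1 <- lv[ok]; b1 <- b[ok]
  a <- c(a1, b1); bb <- c(b1, a1)        # symmetrisation
  tot <- length(a)
  if (tot == 0L) return(glcm_zero_features())
  px <- tabulate(a, Ng) / tot
  i <- seq_len(Ng)
  mux <- sum(i * px)
  varx <- sum((i - mux)^2 * px)
  kd <- 0:(Ng - 1)
  pdiff <- tabulate(abs(a - bb) + 1L, Ng) / tot
  ks <- 2:(2 * Ng)
  psum <- tabulate(a + bb - 1L, 2L * Ng - 1L) / tot
  auto <- (sum(ks^2 * psum) - sum(kd^2 * pdiff)) / 4
  da <- sum(kd * pdiff)
  cnt <- tabulate((a - 1L) * Ng + bb, Ng * Ng)
  pnz <- cnt[cnt > 0] / tot
  HXY <- -sum(pnz * log2(pnz))
  pxnz <- px[px > 0]
  HX <- -sum(pxnz * log2(pxnz))
  nz <- function(v) v[v > 0]
  c(
    Autocorrelation = auto,
    JointAverage = mux,
    ClusterProminence = sum((ks - 2 * mux)^4 * psum),
    ClusterShade = sum((ks - 2 * mux)^3 * psum),
    ClusterTendency = sum((ks - 2 * mux)^2 * psum),
    Contrast = sum(kd^2 * pdiff),
    Correlation = if (varx > 0) (auto - mux^2) / varx else 0,
    DifferenceAverage = da,
    DifferenceEntropy = -sum(nz(pdiff) * log2(nz(pdiff))),
    DifferenceVariance = sum((kd - da)^2 * pdiff),
    JointEnergy = sum(pnz^2),
    JointEntropy = HXY,
    Imc1 = if (HX > 0) (HXY - 2 * HX) / HX else 0,
    Imc2 = sqrt(pmax(1 - exp(-2 * (2 * HX - HXY)), 0)),
    Idm = sum(pdiff / (1 + kd^2)),
    Idmn = sum(pdiff / (1 + kd^2 / Ng^2)),
    Id = sum(pdiff / (1 + kd)),
    Idn = sum(pdiff / (1 + kd / Ng)),
    InverseVariance = sum(pdiff[-1] / kd[-1]^2),
    MaximumProbability = max(pnz),
    SumEntropy = -sum(nz(psum) * log2(nz(psum))),
    SumSquares = sum(i^2 * px) - mux^2,
    MCC = glcm_mcc(cnt, px, Ng)
  )
}

glcm_zero_features <- function() {
  stats::setNames(numeric(23),
                  c("Autocorrelation", "JointAverage", "ClusterProminence",
                    "ClusterShade", "ClusterTendency", "Contrast",
                    "Correlation", "DifferenceAverage", "DifferenceEntropy",
                    "DifferenceVariance", "JointEnergy", "JointEntropy",
                    "Imc1", "Imc2", "Idm", "Idmn", "Id", "Idn",
                    "InverseVariance", "MaximumProbability", "SumEntropy",
                    "SumSquares", "MCC"))
}

glcm_mcc <- function(cnt, px, Ng) {
  keep <- px > 0
  if (sum(keep) < 2L) return(0)
  P <- matrix(cnt / sum(cnt), Ng, Ng, byrow = TRUE)[keep, keep,
                                                    drop = FALSE]
  dhalf <- 1 / sqrt(px[keep])
  S <- P * outer(dhalf, dhalf)
  ev <- sort(abs(eigen(S, symmetric = TRUE, only.values = TRUE)$values),
             decreasing = TRUE)
  ev[2]
}

#' Gray-level run-length features (16 features)
#'
#' Runs of consecutive equal levels are counted along each of the 13 unique
#' 3-D directions (out-of-ROI voxels break runs); the 16 standard features
#' are averaged over directions.
#'
#' @inheritParams compute_glcm_features
#' @param n_voxels number of ROI voxels (for RunPercentage).
#' @return Named numeric vector of 16 features.
#' @export
compute_glrlm_features <- function(lv, Ng, n_voxels = sum(!is.na(lv))) {
  dirs <- directions13()
  acc <- NULL
  for (r in seq_len(nrow(dirs))) {
    R <- glrlm_matrix(lv, Ng, dirs[r, ])
    f <- glrlm_features_one(R, n_voxels)
    acc <- if (is.null(acc)) f else acc + f
  }
  acc / nrow(dirs)
}

# run-length matrix R[level, run length] along direction d
glrlm_matrix <- function(lv, Ng, d) {
  dm <- dim(lv)
  maxd <- max(dm)
  I <- slice.index(lv, 1); J <- slice.index(lv, 2); K <- slice.index(lv, 3)
  # t = p.d is strictly monotone along a line with step |d|^2; the line id
  # q = p*|d|^2 - t*d is invariant under p -> p + s*d
  dd <- sum(d^2)
  t_ <- I * d[1] + J * d[2] + K * d[3]
  q1 <- I * dd - t_ * d[1] + 6L * maxd
  q2 <- J * dd - t_ * d[2] + 6L * maxd
  q3 <- K * dd - t_ * d[3] + 6L * maxd
  stride <- 13 * maxd
  key <- as.numeric(q1) + as.numeric(q2) * stride +
    as.numeric(q3) * stride^2
  ord <- order(key, as.vector(t_))
  v <- as.vector(lv)[ord]
  v[is.na(v)] <- 0
  keyo <- key[ord]
  n <- length(v)
  newrun <- c(TRUE, keyo[-1] != keyo[-n] | v[-1] != v[-n])
  runid <- cumsum(newrun)
  runlen <- tabulate(runid)
  runlev <- v[newrun]
  keep <- runlev > 0
  runlen <- runlen[keep]; runlev <- runlev[keep]
  maxlen <- max(runlen, 1L)
  counts <- tabulate((runlev - 1L) * maxlen + runlen, nbins = Ng * maxlen)
  matrix(counts, Ng, maxlen, byrow = TRUE)
}

glrlm_features_one <- function(R, n_voxels) {
  Nr <- sum(R)
  p <- R / Nr
  i <- row(R); j <- col(R)
  ivec <- seq_len(nrow(R)); jvec <- seq_len(ncol(R))
  pg <- rowSums(R); pr <- colSums(R)
  mui <- sum(i * p); muj <- sum(j * p)
  nzp <- p[p > 0]
  c(
    GrayLevelNonUniformity = sum(pg^2) / Nr,
    GrayLevelNonUniformityNormalized = sum(pg^2) / Nr^2,
    GrayLevelVariance = sum((i - mui)^2 * p),
    HighGrayLevelRunEmphasis = sum(i^2 * p),
    LongRunEmphasis = sum(j^2 * p),
    LongRunHighGrayLevelEmphasis = sum(i^2 * j^2 * p),
    LongRunLowGrayLevelEmphasis = sum(j^2 * p / i^2),
    LowGrayLevelRunEmphasis = sum(p / i^2),
    RunEntropy = -sum(nzp * log2(nzp)),
    RunLengthNonUniformity = sum(pr^2) / Nr,
    RunLengthNonUniformityNormalized = sum(pr^2) / Nr^2,
    RunPercentage = Nr / n_voxels,
    RunVariance = sum((j - muj)^2 * p),
    ShortRunEmphasis = sum(p / j^2),
    ShortRunHighGrayLevelEmphasis = sum(i^2 * p / j^2),
    ShortRunLowGrayLevelEmphasis = sum(p / (i^2 * j^2))
  )
}

#' Gray-level size-zone features (16 features)
#'
#' Zones are 26-connected components of equal gray level; the zone matrix
#' counts zones by (level, size). Connected components are found on the
#' equal-level adjacency graph.
#'
#' @inheritParams compute_glrlm_features
#' @return Named numeric vector of 16 features.
#' @export
compute_glszm_features <- function(lv, Ng, n_voxels = sum(!is.na(lv))) {
  zones <- label_zones(lv)
  Z <- zones$matrix(Ng)
  glszm_features_one(Z, n_voxels)
}

# 26-connected equal-level components; returns zone sizes and levels
label_zones <- function(lv) {
  roi_lin <- which(!is.na(lv))
  rank_of <- array(NA_integer_, dim(lv))
  rank_of[roi_lin] <- seq_along(roi_lin)
  dirs <- directions13()
  efrom <- integer(0); eto <- integer(0)
  for (r in seq_len(nrow(dirs))) {
    b <- shift_array(lv, dirs[r, ])
    rb <- shift_array(rank_of, dirs[r, ])
    ok <- !is.na(lv) & !is.na(b) & lv == b
    if (any(ok)) {
      efrom <- c(efrom, rank_of[ok])
      eto <- c(eto, rb[ok])
    }
  }
  g <- igraph::make_empty_graph(n = length(roi_lin), directed = FALSE)
  if (length(efrom))
    g <- igraph::add_edges(g, rbind(efrom, eto))
  memb <- igraph::components(g)$membership
  sizes <- tabulate(memb)
  lvls <- lv[roi_lin][match(seq_along(sizes), memb)]
  list(
    sizes = sizes, levels = lvls,
    matrix = function(Ng) {
      maxs <- max(sizes)
      counts <- tabulate((lvls - 1L) * maxs + sizes, nbins = Ng * maxs)
      matrix(counts, Ng, maxs, byrow = TRUE)
    })
}

glszm_features_one <- function(Z, n_voxels) {
  Nz <- sum(Z)
  p <- Z / Nz
  i <- row(Z); s <- col(Z)
  pg <- rowSums(Z); ps <- colSums(Z)
  mui <- sum(i * p); mus <- sum(s * p)
  nzp <- p[p > 0]
  c(
    GrayLevelNonUniformity = sum(pg^2) / Nz,
    GrayLevelNonUniformityNormalized = sum(pg^2) / Nz^2,
    GrayLevelVariance = sum((i - mui)^2 * p),
    HighGrayLevelZoneEmphasis = sum(i^2 * p),
    LargeAreaEmphasis = sum(s^2 * p),
    LargeAreaHighGrayLevelEmphasis = sum(i^2 * s^2 * p),
    LargeAreaLowGrayLevelEmphasis = sum(s^2 * p / i^2),
    LowGrayLevelZoneEmphasis = sum(p / i^2),
    SizeZoneNonUniformity = sum(ps^2) / Nz,
    SizeZoneNonUniformityNormalized = sum(ps^2) / Nz^2,
    SmallAreaEmphasis = sum(p / s^2),
    SmallAreaHighGrayLevelEmphasis = sum(i^2 * p / s^2),
    SmallAreaLowGrayLevelEmphasis = sum(p / (i^2 * s^2)),
    ZoneEntropy = -sum(nzp * log2(nzp)),
    ZonePercentage = Nz / n_voxels,
    ZoneVariance = sum((s - mus)^2 * p)
  )
}

#' Gray-level dependence features (14 features)
#'
#' The dependence of a voxel is the number of its in-ROI 26-neighbours whose
#' level differs from its own by at most `alpha`; the dependence matrix
#' counts voxels by (level, dependence).
#'
#' @inheritParams compute_glcm_features
#' @param alpha dependence tolerance in gray levels (default 0).
#' @return Named numeric vector of 14 features.
#' @export
compute_gldm_features <- function(lv, Ng, alpha = 0) {
  dep <- array(0L, dim(lv))
  dirs <- directions26()
  for (r in seq_len(nrow(dirs))) {
    b <- shift_array(lv, dirs[r, ])
    dep <- dep + (!is.na(lv) & !is.na(b) & abs(lv - b) <= alpha)
  }
  inroi <- !is.na(lv)
  maxd <- max(dep[inroi]) + 1L
  counts <- tabulate((lv[inroi] - 1L) * maxd + dep[inroi] + 1L,
                     nbins = Ng * maxd)
  D <- matrix(counts, Ng, maxd, byrow = TRUE)
  gldm_features_one(D)
}

gldm_features_one <- function(D) {
  Nz <- sum(D)
  p <- D / Nz
  i <- row(D); j <- col(D)   # j = dependence + 1
  pg <- rowSums(D); pd <- colSums(D)
  mui <- sum(i * p); muj <- sum(j * p)
  nzp <- p[p > 0]
  c(
    DependenceEntropy = -sum(nzp * log2(nzp)),
    DependenceNonUniformity = sum(pd^2) / Nz,
    DependenceNonUniformityNormalized = sum(pd^2) / Nz^2,
    DependenceVariance = sum((j - muj)^2 * p),
    GrayLevelNonUniformity = sum(pg^2) / Nz,
    GrayLevelVariance = sum((i - mui)^2 * p),
    HighGrayLevelEmphasis = sum(i^2 * p),
    LargeDependenceEmphasis = sum(j^2 * p),
    LargeDependenceHighGrayLevelEmphasis = sum(i^2 * j^2 * p),
    LargeDependenceLowGrayLevelEmphasis = sum(j^2 * p / i^2),
    LowGrayLevelEmphasis = sum(p / i^2),
    SmallDependenceEmphasis = sum(p / j^2),
    SmallDependenceHighGrayLevelEmphasis = sum(i^2 * p / j^2),
    SmallDependenceLowGrayLevelEmphasis = sum(p / (i^2 * j^2))
  )
}

#' Neighbouring gray-tone difference features (5 features)
#'
#' For each level i, `s_i` sums the absolute difference between i and the
#' mean level of each member voxel's valid 26-neighbourhood. Voxels with no
#' in-ROI neighbour are excluded.
#'
#' @inheritParams compute_glcm_features
#' @return Named numeric vector of 5 features
#'   (Coarseness, Contrast, Busyness, Complexity, Strength).
#' @export
compute_ngtdm_features <- function(lv, Ng) {
  nsum <- array(0, dim(lv))
  ncnt <- array(0L, dim(lv))
  dirs <- directions26()
  for (r in seq_len(nrow(dirs))) {
    b <- shift_array(lv, dirs[r, ])
    ok <- !is.na(b)
    nsum[ok] <- nsum[ok] + b[ok]
    ncnt <- ncnt + ok
  }
  valid <- !is.na(lv) & ncnt > 0L
  li <- lv[valid]
  diffs <- abs(li - nsum[valid] / ncnt[valid])
  s <- group_sum(diffs, li, Ng)
  n_i <- tabulate(li, nbins = Ng)
  Nvp <- sum(n_i)
  p <- n_i / Nvp
  act <- which(p > 0)
  Ngp <- length(act)
  coars_den <- sum(p * s)
  coarseness <- if (coars_den > 0) 1 / coars_den else COARSENESS_CAP
  coarseness <- min(coarseness, COARSENESS_CAP)
  if (Ngp > 1) {
    pa <- p[act]; sa <- s[act]; ia <- act
    dd2 <- outer(ia, ia, function(a, b) (a - b)^2)
    contrast <- sum(outer(pa, pa) * dd2) / (Ngp * (Ngp - 1)) * sum(s) / Nvp
    busy_den <- sum(abs(outer(ia * pa, ia * pa, `-`)))
    busyness <- if (busy_den > 0) sum(p * s) / busy_den else 0
    num_c <- outer(pa * sa, pa * sa, `+`)
    den_c <- outer(pa, pa, `+`)
    complexity <- sum(abs(outer(ia, ia, `-`)) * num_c / den_c) / Nvp
    s_tot <- sum(s)
    strength <- if (s_tot > 0) sum(den_c * dd2) / s_tot else 0
  } else {
    contrast <- 0; busyness <- 0; complexity <- 0; strength <- 0
  }
  c(Coarseness = coarseness, Contrast = contrast, Busyness = busyness,
    Complexity = complexity, Strength = strength)
}
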