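# Brute-force oracles for the texture-matrix families. These enumerate voxel
# pairs / neighbourhoods / runs / zones literally, voxel by voxel, and apply
# the textbook feature formulas on dense matrices. They share no accumulation
# code with the package implementation.

oracle_dirs13 <- rbind(
  c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
  c(1, 1, 0), c(1, -1, 0), c(1, 0, 1), c(1, 0, -1),
  c(0, 1, 1), c(0, 1, -1),
  c(1, 1, 1), c(1, 1, -1), c(1, -1, 1), c(1, -1, -1))

oracle_neighbours26 <- local({
  g <- expand.grid(-1:1, -1:1, -1:1)
  as.matrix(g[!(g[, 1] == 0 & g[, 2] == 0 & g[, 3] == 0), ])
})

in_bounds <- function(p, dm) all(p >= 1) && all(p <= dm)

# random small discretised ROI: list(lv = level array with NA outside, Ng)
random_roi <- function(seed, max_dim = 5L, n_levels = 4L) {
  set.seed(seed)
  dm <- sample(2:max_dim, 3L, replace = TRUE)
  lv <- array(sample(seq_len(n_levels), prod(dm), replace = TRUE), dm)
  drop_mask <- array(stats::runif(prod(dm)) < 0.3, dm)
  if (sum(!drop_mask) < 2L) drop_mask[seq_len(2)] <- FALSE
  lv[drop_mask] <- NA
  # re-map so levels are 1..Ng with both extremes present (as produced by
  # fixed-bin-width discretisation)
  present <- sort(unique(lv[!is.na(lv)]))
  lv[] <- match(lv, present)
  list(lv = lv, Ng = length(present))
}

oracle_glcm <- function(lv, Ng, distance = 1L) {
  dm <- dim(lv)
  feats <- NULL
  for (r in seq_len(nrow(oracle_dirs13))) {
    d <- oracle_dirs13[r, ] * distance
    M <- matrix(0, Ng, Ng)
    for (x in seq_len(dm[1])) for (y in seq_len(dm[2]))
      for (z in seq_len(dm[3])) {
        if (is.na(lv[x, y, z])) next
        for (sgn in c(1, -1)) {
          q <- c(x, y, z) + sgn * d
          if (!in_bounds(q, dm)) next
          w <- lv[q[1], q[2], q[3]]
          if (is.na(w)) next
          M[lv[x, y, z], w] <- M[lv[x, y, z], w] + 1
        }
      }
    f <- oracle_glcm_features(M / max(sum(M), 1))
    feats <- if (is.null(feats)) f else feats + f
  }
  feats / nrow(oracle_dirs13)
}

oracle_glcm_features <- function(P) {
  Ng <- nrow(P)
  px <- rowSums(P); py <- colSums(P)
  i <- seq_len(Ng)
  mux <- sum(i * px); muy <- sum(i * py)
  sx <- sqrt(sum((i - mux)^2 * px)); sy <- sqrt(sum((i - muy)^2 * py))
  auto <- 0; contrast <- 0; cp <- 0; cs <- 0; ct <- 0
  idm <- 0; idmn <- 0; id <- 0; idn <- 0; iv <- 0; ss <- 0
  je <- 0; jent <- 0
  pdiff <- numeric(Ng); psum <- numeric(2 * Ng - 1)
  for (a in i) for (b in i) {
    p <- P[a, b]
    auto <- auto + a * b * p
    contrast <- contrast + (a - b)^2 * p
    cp <- cp + (a + b - mux - muy)^4 * p
    cs <- cs + (a + b - mux - muy)^3 * p
    ct <- ct + (a + b - mux - muy)^2 * p
    idm <- idm + p / (1 + (a - b)^2)
    idmn <- idmn + p / (1 + (a - b)^2 / Ng^2)
    id <- id + p / (1 + abs(a - b))
    idn <- idn + p / (1 + abs(a - b) / Ng)
    if (a != b) iv <- iv + p / (a - b)^2
    ss <- ss + (a - mux)^2 * p
    je <- je + p^2
    if (p > 0) jent <- jent - p * log2(p)
    pdiff[abs(a - b) + 1] <- pdiff[abs(a - b) + 1] + p
    psum[a + b - 1] <- psum[a + b - 1] + p
  }
  da <- sum((0:(Ng - 1)) * pdiff)
  dent <- -sum(pdiff[pdiff > 0] * log2(pdiff[pdiff > 0]))
  dvar <- sum(((0:(Ng - 1)) - da)^2 * pdiff)
  sent <- -sum(psum[psum > 0] * log2(psum[psum > 0]))
  HX <- -sum(px[px > 0] * log2(px[px > 0]))
  HY <- -sum(py[py > 0] * log2(py[py > 0]))
  HXY <- jent
  HXY1 <- 0; HXY2 <- 0
  for (a in i) for (b in i) {
    pq <- px[a] * py[b]
    if (pq > 0) {
      if (P[a, b] > 0) HXY1 <- HXY1 - P[a, b] * log2(pq)
      HXY2 <- HXY2 - pq * log2(pq)
    }
  }
  imc1 <- if (max(HX, HY) > 0) (HXY - HXY1) / max(HX, HY) else 0
  imc2 <- sqrt(max(1 - exp(-2 * (HXY2 - HXY)), 0))
  # MCC via the literal Q matrix and a general eigendecomposition
  keep <- which(px > 0)
  mcc <- 0
  if (length(keep) >= 2) {
    Q <- matrix(0, length(keep), length(keep))
    for (ai in seq_along(keep)) for (bi in seq_along(keep)) {
      s <- 0
      for (ki in seq_along(keep)) {
        s <- s + P[keep[ai], keep[ki]] * P[keep[bi], keep[ki]] /
          (px[keep[ai]] * py[keep[ki]])
      }
      Q[ai, bi] <- s
    }
    ev <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
    mcc <- sqrt(max(ev[2], 0))
  }
  c(Autocorrelation = auto, JointAverage = mux, ClusterProminence = cp,
    ClusterShade = cs, ClusterTendency = ct, Contrast = contrast,
    Correlation = if (sx * sy > 0) (auto - mux * muy) / (sx * sy) else 0,
    DifferenceAverage = da, DifferenceEntropy = dent,
    DifferenceVariance = dvar, JointEnergy = je, JointEntropy = jent,
    Imc1 = imc1, Imc2 = imc2, Idm = idm, Idmn = idmn, Id = id, Idn = idn,
    InverseVariance = iv, MaximumProbability = max(P), SumEntropy = sent,
    SumSquares = ss, MCC = mcc)
}

oracle_glrlm <- function(lv, Ng) {
  dm <- dim(lv)
  n_voxels <- sum(!is.na(lv))
  feats <- NULL
  for (r in seq_len(nrow(oracle_dirs13))) {
    d <- oracle_dirs13[r, ]
    runs <- list()
    for (x in seq_len(dm[1])) for (y in seq_len(dm[2]))
      for (z in seq_len(dm[3])) {
        v <- lv[x, y, z]
        if (is.na(v)) next
        prev <- c(x, y, z) - d
        if (in_bounds(prev, dm) &&
            !is.na(lv[prev[1], prev[2], prev[3]]) &&
            lv[prev[1], prev[2], prev[3]] == v) next  # not a run start
        len <- 1L
        nxt <- c(x, y, z) + d
        while (in_bounds(nxt, dm) && !is.na(lv[nxt[1], nxt[2], nxt[3]]) &&
               lv[nxt[1], nxt[2], nxt[3]] == v) {
          len <- len + 1L
          nxt <- nxt + d
        }
        runs[[length(runs) + 1L]] <- c(v, len)
      }
    runs <- do.call(rbind, runs)
    R <- matrix(0, Ng, max(runs[, 2]))
    for (k in seq_len(nrow(runs)))
      R[runs[k, 1], runs[k, 2]] <- R[runs[k, 1], runs[k, 2]] + 1
    f <- oracle_rl_features(R, n_voxels)
    feats <- if (is.null(feats)) f else feats + f
  }
  feats / nrow(oracle_dirs13)
}

oracle_rl_features <- function(R, n_voxels) {
  Nr <- sum(R)
  p <- R / Nr
  out <- c(GrayLevelNonUniformity = 0, GrayLevelNonUniformityNormalized = 0,
           GrayLevelVariance = 0, HighGrayLevelRunEmphasis = 0,
           LongRunEmphasis = 0, LongRunHighGrayLevelEmphasis = 0,
           LongRunLowGrayLevelEmphasis = 0, LowGrayLevelRunEmphasis = 0,
           RunEntropy = 0, RunLengthNonUniformity = 0,
           RunLengthNonUniformityNormalized = 0, RunPercentage = Nr / n_voxels,
           RunVariance = 0, ShortRunEmphasis = 0,
           ShortRunHighGrayLevelEmphasis = 0,
           ShortRunLowGrayLevelEmphasis = 0)
  mui <- 0; muj <- 0
  for (a in seq_len(nrow(R))) for (l in seq_len(ncol(R))) {
    mui <- mui + a * p[a, l]; muj <- muj + l * p[a, l]
  }
  for (a in seq_len(nrow(R))) for (l in seq_len(ncol(R))) {
    q <- p[a, l]
    out["GrayLevelVariance"] <- out["GrayLevelVariance"] + (a - mui)^2 * q
    out["HighGrayLevelRunEmphasis"] <-
      out["HighGrayLevelRunEmphasis"] + a^2 * q
    out["LongRunEmphasis"] <- out["LongRunEmphasis"] + l^2 * q
    out["LongRunHighGrayLevelEmphasis"] <-
      out["LongRunHighGrayLevelEmphasis"] + a^2 * l^2 * q
    out["LongRunLowGrayLevelEmphasis"] <-
      out["LongRunLowGrayLevelEmphasis"] + l^2 * q / a^2
    out["LowGrayLevelRunEmphasis"] <-
      out["LowGrayLevelRunEmphasis"] + q / a^2
    if (q > 0) out["RunEntropy"] <- out["RunEntropy"] - q * log2(q)
    out["RunVariance"] <- out["RunVariance"] + (l - muj)^2 * q
    out["ShortRunEmphasis"] <- out["ShortRunEmphasis"] + q / l^2
    out["ShortRunHighGrayLevelEmphasis"] <-
      out["ShortRunHighGrayLevelEmphasis"] + a^2 * q / l^2
    out["ShortRunLowGrayLevelEmphasis"] <-
      out["ShortRunLowGrayLevelEmphasis"] + q / (a^2 * l^2)
  }
  out["GrayLevelNonUniformity"] <- sum(rowSums(R)^2) / Nr
  out["GrayLevelNonUniformityNormalized"] <- sum(rowSums(R)^2) / Nr^2
  out["RunLengthNonUniformity"] <- sum(colSums(R)^2) / Nr
  out["RunLengthNonUniformityNormalized"] <- sum(colSums(R)^2) / Nr^2
  out
}

# flood-fill zone labelling (26-connected components of equal level)
oracle_zones <- function(lv) {
  dm <- dim(lv)
  seen <- array(FALSE, dm)
  zones <- list()
  for (x in seq_len(dm[1])) for (y in seq_len(dm[2]))
    for (z in seq_len(dm[3])) {
      if (is.na(lv[x, y, z]) || seen[x, y, z]) next
      level <- lv[x, y, z]
      stack <- list(c(x, y, z))
      seen[x, y, z] <- TRUE
      size <- 0L
      while (length(stack)) {
        p <- stack[[length(stack)]]
        stack[[length(stack)]] <- NULL
        size <- size + 1L
        for (r in seq_len(nrow(oracle_neighbours26))) {
          q <- p + oracle_neighbours26[r, ]
          if (!in_bounds(q, dm)) next
          if (seen[q[1], q[2], q[3]]) next
          w <- lv[q[1], q[2], q[3]]
          if (!is.na(w) && w == level) {
            seen[q[1], q[2], q[3]] <- TRUE
            stack[[length(stack) + 1L]] <- q
          }
        }
      }
      zones[[length(zones) + 1L]] <- c(level, size)
    }
  do.call(rbind, zones)
}

oracle_glszm <- function(lv, Ng) {
  zones <- oracle_zones(lv)
  Z <- matrix(0, Ng, max(zones[, 2]))
  for (k in seq_len(nrow(zones)))
    Z[zones[k, 1], zones[k, 2]] <- Z[zones[k, 1], zones[k, 2]] + 1
  n_voxels <- sum(!is.na(lv))
  Nz <- sum(Z)
  p <- Z / Nz
  i <- row(Z); s <- col(Z)
  mui <- sum(i * p); mus <- sum(s * p)
  nzp <- p[p > 0]
  c(GrayLevelNonUniformity = sum(rowSums(Z)^2) / Nz,
    GrayLevelNonUniformityNormalized = sum(rowSums(Z)^2) / Nz^2,
    GrayLevelVariance = sum((i - mui)^2 * p),
    HighGrayLevelZoneEmphasis = sum(i^2 * p),
    LargeAreaEmphasis = sum(s^2 * p),
    LargeAreaHighGrayLevelEmphasis = sum(i^2 * s^2 * p),
    LargeAreaLowGrayLevelEmphasis = sum(s^2 * p / i^2),
    LowGrayLevelZoneEmphasis = sum(p / i^2),
    SizeZoneNonUniformity = sum(colSums(Z)^2) / Nz,
    SizeZoneNonUniformityNormalized = sum(colSums(Z)^2) / Nz^2,
    SmallAreaEmphasis = sum(p / s^2),
    SmallAreaHighGrayLevelEmphasis = sum(i^2 * p / s^2),
    SmallAreaLowGrayLevelEmphasis = sum(p / (i^2 * s^2)),
    ZoneEntropy = -sum(nzp * log2(nzp)),
    ZonePercentage = Nz / n_voxels,
    ZoneVariance = sum((s - mus)^2 * p))
}

oracle_gldm <- function(lv, Ng, alpha = 0) {
  dm <- dim(lv)
  recs <- list()
  for (x in seq_len(dm[1])) for (y in seq_len(dm[2]))
    for (z in seq_len(dm[3])) {
      v <- lv[x, y, z]
      if (is.na(v)) next
      dep <- 0L
      for (r in seq_len(nrow(oracle_neighbours26))) {
        q <- c(x, y, z) + oracle_neighbours26[r, ]
        if (!in_bounds(q, dm)) next
        w <- lv[q[1], q[2], q[3]]
        if (!is.na(w) && abs(w - v) <= alpha) dep <- dep + 1L
      }
      recs[[length(recs) + 1L]] <- c(v, dep)
    }
  recs <- do.call(rbind, recs)
  D <- matrix(0, Ng, max(recs[, 2]) + 1L)
  for (k in seq_len(nrow(recs)))
    D[recs[k, 1], recs[k, 2] + 1L] <- D[recs[k, 1], recs[k, 2] + 1L] + 1
  Nz <- sum(D)
  p <- D / Nz
  i <- row(D); j <- col(D)
  mui <- sum(i * p); muj <- sum(j * p)
  nzp <- p[p > 0]
  c(DependenceEntropy = -sum(nzp * log2(nzp)),
    DependenceNonUniformity = sum(colSums(D)^2) / Nz,
    DependenceNonUniformityNormalized = sum(colSums(D)^2) / Nz^2,
    DependenceVariance = sum((j - muj)^2 * p),
    GrayLevelNonUniformity = sum(rowSums(D)^2) / Nz,
    GrayLevelVariance = sum((i - mui)^2 * p),
    HighGrayLevelEmphasis = sum(i^2 * p),
    LargeDependenceEmphasis = sum(j^2 * p),
    LargeDependenceHighGrayLevelEmphasis = sum(i^2 * j^2 * p),
    LargeDependenceLowGrayLevelEmphasis = sum(j^2 * p / i^2),
    LowGrayLevelEmphasis = sum(p / i^2),
    SmallDependenceEmphasis = sum(p / j^2),
    SmallDependenceHighGrayLevelEmphasis = sum(i^2 * p / j^2),
    SmallDependenceLowGrayLevelEmphasis = sum(p / (i^2 * j^2)))
}

oracle_ngtdm <- function(lv, Ng) {
  dm <- dim(lv)
  s <- numeric(Ng); n_i <- numeric(Ng)
  for (x in seq_len(dm[1])) for (y in seq_len(dm[2]))
    for (z in seq_len(dm[3])) {
      v <- lv[x, y, z]
      if (is.na(v)) next
      nb <- c()
      for (r in seq_len(nrow(oracle_neighbours26))) {
        q <- c(x, y, z) + oracle_neighbours26[r, ]
        if (!in_bounds(q, dm)) next
        w <- lv[q[1], q[2], q[3]]
        if (!is.na(w)) nb <- c(nb, w)
      }
      if (!length(nb)) next
      n_i[v] <- n_i[v] + 1
      s[v] <- s[v] + abs(v - mean(nb))
    }
  Nvp <- sum(n_i)
  p <- n_i / Nvp
  act <- which(p > 0)
  Ngp <- length(act)
  coars_den <- sum(p * s)
  coarseness <- min(if (coars_den > 0) 1 / coars_den else 1e6, 1e6)
  contrast <- 0; busy_den <- 0; complexity <- 0; strength <- 0
  if (Ngp > 1) {
    for (a in act) for (b in act) {
      contrast <- contrast + p[a] * p[b] * (a - b)^2
      busy_den <- busy_den + abs(a * p[a] - b * p[b])
      complexity <- complexity +
        abs(a - b) * (p[a] * s[a] + p[b] * s[b]) / (p[a] + p[b])
      strength <- strength + (p[a] + p[b]) * (a - b)^2
    }
    contrast <- contrast / (Ngp * (Ngp - 1)) * sum(s) / Nvp
    complexity <- complexity / Nvp
    strength <- if (sum(s) > 0) strength / sum(s) else 0
  }
  busyness <- if (busy_den > 0) sum(p * s) / busy_den else 0
  c(Coarseness = coarseness, Contrast = contrast, Busyness = busyness,
    Complexity = complexity, Strength = strength)
}

# naive first-order oracle with manual linear-interpolation percentiles
oracle_first_order <- function(x, levels, Ng, voxel_volume) {
  n <- length(x)
  pctl <- function(q) {
    xs <- sort(x)
    h <- (n - 1) * q + 1
    lo <- floor(h); hi <- ceiling(h)
    xs[lo] + (h - lo) * (xs[hi] - xs[lo])
  }
  p <- as.numeric(table(factor(levels, levels = seq_len(Ng)))) / n
  p <- p[p > 0]
  mu <- sum(x) / n
  m2 <- sum((x - mu)^2) / n
  sub <- x[x >= pctl(.1) & x <= pctl(.9)]
  c(Energy = sum(x^2), TotalEnergy = voxel_volume * sum(x^2),
    Entropy = -sum(p * log2(p)), Minimum = min(x),
    `10Percentile` = pctl(.1), `90Percentile` = pctl(.9), Maximum = max(x),
    Mean = mu, Median = pctl(.5),
    InterquartileRange = pctl(.75) - pctl(.25), Range = max(x) - min(x),
    MeanAbsoluteDeviation = sum(abs(x - mu)) / n,
    RobustMeanAbsoluteDeviation = mean(abs(sub - mean(sub))),
    RootMeanSquared = sqrt(sum(x^2) / n),
    Skewness = if (m2 > 0) (sum((x - mu)^3) / n) / m2^1.5 else 0,
    Kurtosis = if (m2 > 0) (sum((x - mu)^4) / n) / m2^2 else 0,
    Variance = m2, Uniformity = sum(p^2))
}
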