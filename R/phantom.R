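# Digital stand-ins for the physical objects of the study: a tissue-
# equivalent mouse phantom (soft tissue / lung / bone compartments), a
# Perspex texture phantom with cylindrical density inserts, and two-arm
# tumour cohorts. Geometry is deliberately simple (ellipsoids, cylinders,
# spheres): the goal is controlled intensity statistics for downstream
# reliability screening, not anatomical realism.

# Affine density -> intensity calibration for the density-driven presets,
# anchored so soft tissue (1.01 g/cm^3) sits at 16800 scanner units, the
# scale observed for mouse soft tissue on this class of scanner.
DENSITY_SLOPE <- 12000
DENSITY_OFFSET <- 4680

#' Convert material density to scanner intensity
#' @param density g/cm^3.
#' @return Scanner units under the package's affine calibration.
#' @export
density_to_intensity <- function(density) {
  DENSITY_SLOPE * density + DENSITY_OFFSET
}

#' Material description for phantom compartments
#'
#' @param label material name.
#' @param density physical density in g/cm^3 (> 0 for non-air materials).
#' @param mean_intensity mean scanner intensity; defaults to the affine
#'   density calibration ([density_to_intensity()]).
#' @param texture_sd standard deviation of the material's intrinsic intensity
#'   texture (scanner units). This is a property of the object, shared by
#'   scan and rescan.
#' @param correlation_length spatial correlation length of the texture in mm
#'   (0 = white).
#' @return An object of class `material_spec`.
#' @export
material_spec <- function(label, density, mean_intensity = NULL,
                          texture_sd = 0, correlation_length = 0) {
  if (!identical(label, "air") && (!is.finite(density) || density <= 0))
    stop("material_spec: density must be > 0 for non-air materials")
  if (is.null(mean_intensity)) mean_intensity <- density_to_intensity(density)
  if (!is.finite(mean_intensity))
    stop("material_spec: mean_intensity must be finite")
  if (texture_sd < 0) stop("material_spec: texture_sd must be >= 0")
  structure(list(label = label, density = density,
                 mean_intensity = mean_intensity, texture_sd = texture_sd,
                 correlation_length = correlation_length),
            class = "material_spec")
}

#' Default mouse-phantom materials
#'
#' Densities follow the tissue-equivalent phantom: bone 1.39, lung 0.68 and
#' soft tissue 1.01 g/cm^3, mapped to intensity by the affine calibration.
#' Air fills the space around the body.
#' @return Named list of [material_spec()]s (air, soft_tissue, lung, bone).
#' @export
mouse_materials <- function() {
  list(
    air = material_spec("air", 0.0012, mean_intensity = 1861,
                        texture_sd = 60, correlation_length = 0),
    soft_tissue = material_spec("soft_tissue", 1.01, texture_sd = 350,
                                correlation_length = 0.5),
    lung = material_spec("lung", 0.68, texture_sd = 450,
                         correlation_length = 0.35),
    bone = material_spec("bone", 1.39, texture_sd = 250,
                         correlation_length = 0.3)
  )
}

#' Default texture-phantom inserts
#'
#' The four cylindrical inserts of the Perspex texture phantom with their
#' observed mean scanner intensities: air 1861, solid water (1.05 g/cm^3)
#' 2940, PVC (1.47) 4138, acetal (1.52) 2917.
#' @return Named list of [material_spec()]s.
#' @export
texture_inserts <- function() {
  list(
    air = material_spec("air", 0.0012, mean_intensity = 1861,
                        texture_sd = 60, correlation_length = 0),
    solid_water = material_spec("solid_water", 1.05, mean_intensity = 2940,
                                texture_sd = 110, correlation_length = 0.45),
    pvc = material_spec("pvc", 1.47, mean_intensity = 4138,
                        texture_sd = 180, correlation_length = 0.4),
    acetal = material_spec("acetal", 1.52, mean_intensity = 2917,
                           texture_sd = 140, correlation_length = 0.35)
  )
}

#' Imaging-protocol description
#'
#' Emulates the protocol-dependent image degradation of cone-beam CT at 40,
#' 50 or 60 kV: lower tube voltage means more noise and artefact. Only noise,
#' contrast scaling and a slowly varying bias field are modelled - no
#' projection or beam-hardening physics.
#'
#' @param energy one of 40, 50, 60 (kV label).
#' @param noise_sd per-scan white-noise standard deviation (scanner units,
#'   >= 0).
#' @param contrast_scale multiplicative contrast factor (> 0).
#' @param bias_amplitude standard deviation of the smooth per-scan bias
#'   field (scanner units, >= 0).
#' @return An object of class `scan_protocol`.
#' @export
scan_protocol <- function(energy = 60, noise_sd = NULL,
                          contrast_scale = NULL, bias_amplitude = NULL) {
  if (!energy %in% c(40, 50, 60))
    stop("scan_protocol: energy must be one of 40, 50, 60 kV")
  presets <- list(
    `40` = list(noise_sd = 300, contrast_scale = 1.10, bias_amplitude = 120),
    `50` = list(noise_sd = 200, contrast_scale = 1.05, bias_amplitude = 80),
    `60` = list(noise_sd = 140, contrast_scale = 1.00, bias_amplitude = 50))
  p <- presets[[as.character(energy)]]
  noise_sd <- noise_sd %||% p$noise_sd
  contrast_scale <- contrast_scale %||% p$contrast_scale
  bias_amplitude <- bias_amplitude %||% p$bias_amplitude
  if (!is.finite(noise_sd) || noise_sd < 0)
    stop("scan_protocol: noise_sd must be >= 0")
  if (!is.finite(contrast_scale) || contrast_scale <= 0)
    stop("scan_protocol: contrast_scale must be > 0")
  if (!is.finite(bias_amplitude) || bias_amplitude < 0)
    stop("scan_protocol: bias_amplitude must be >= 0")
  structure(list(energy = energy, noise_sd = noise_sd,
                 contrast_scale = contrast_scale,
                 bias_amplitude = bias_amplitude),
            class = "scan_protocol")
}

# correlated, exactly standardised noise field over a region
texture_field <- function(dm, spacing, sd, corr_len, region = NULL) {
  w <- array(stats::rnorm(prod(dm)), dm)
  if (corr_len > 0) w <- gaussian_smooth(w, corr_len / spacing)
  if (is.null(region)) region <- array(TRUE, dm)
  v <- w[region]
  if (length(v) > 1L && stats::sd(v) > 0) {
    w[region] <- (v - mean(v)) / stats::sd(v) * sd
  } else {
    w[region] <- 0
  }
  w
}

draw_subseeds <- function(seed, n) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed",
                                                     .GlobalEnv) else NULL
  set.seed(seed)
  s <- sample.int(.Machine$integer.max - 1L, n)
  if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  s
}

#' Generate the digital mouse phantom
#'
#' An ellipsoidal soft-tissue body containing two ellipsoidal lungs and a
#' cylindrical spine, surrounded by air, on the requested grid. Compartment
#' mean intensities follow the affine density calibration; each compartment
#' carries its own spatially correlated intrinsic texture (a fixed property
#' of the object, identical across subsequent simulated scans).
#'
#' @param grid a [grid_spec()]; needs at least 8 voxels and 4 mm extent per
#'   axis to place the compartments.
#' @param materials named list with entries `air`, `soft_tissue`, `lung`,
#'   `bone` (see [mouse_materials()]).
#' @param seed integer seed; identical seeds give bit-identical phantoms.
#' @return List with `image` (a [voxel_image()]) and `labels` (integer array:
#'   0 air, 1 soft tissue, 2 lung, 3 bone).
#' @export
generate_mouse_phantom <- function(grid, materials = mouse_materials(),
                                   seed = 1L) {
  stopifnot(inherits(grid, "grid_spec"))
  need <- c("air", "soft_tissue", "lung", "bone")
  if (!all(need %in% names(materials)))
    stop("generate_mouse_phantom: materials must cover ",
         paste(need, collapse = ", "))
  extent <- grid$shape * grid$spacing
  if (any(grid$shape < 8L) || any(extent < 4))
    stop("generate_mouse_phantom: grid too small to place body, lung and ",
         "bone compartments (need >= 8 voxels and >= 4 mm per axis)")
  ax <- lapply(1:3, function(a)
    grid$origin[a] + (seq_len(grid$shape[a]) - 1) * grid$spacing[a])
  ctr <- grid$origin + (grid$shape - 1) * grid$spacing / 2
  X <- array(ax[[1]], grid$shape) - ctr[1]
  Y <- aperm(array(ax[[2]], grid$shape[c(2, 1, 3)]), c(2, 1, 3)) - ctr[2]
  Z <- aperm(array(ax[[3]], grid$shape[c(3, 2, 1)]), c(3, 2, 1)) - ctr[3]
  half <- extent / 2
  body_ax <- 0.92 * half
  inside_ell <- function(cx, cy, cz, a, b, c_) {
    (X - cx)^2 / a^2 + (Y - cy)^2 / b^2 + (Z - cz)^2 / c_^2 <= 1
  }
  labels <- array(0L, grid$shape)
  labels[inside_ell(0, 0, 0, body_ax[1], body_ax[2], body_ax[3])] <- 1L
  lung_a <- pmin(c(0.22, 0.26, 0.30) * extent, c(3.2, 3.6, 4.2))
  lung_off <- 0.27 * extent[1]
  lung_z <- 0.38 * extent[3]
  for (sgn in c(-1, 1)) {
    sel <- inside_ell(sgn * lung_off, 0, lung_z,
                      lung_a[1], lung_a[2], lung_a[3]) & labels == 1L
    labels[sel] <- 2L
  }
  spine_r <- min(0.06 * extent[1], 1.0)
  spine_y <- 0.62 * body_ax[2]
  spine <- (X^2 + (Y - spine_y)^2) <= spine_r^2 &
    abs(Z) <= 0.85 * body_ax[3] & labels == 1L
  labels[spine] <- 3L
  if (!all(1:3 %in% labels))
    stop("generate_mouse_phantom: grid too small to place body, lung and ",
         "bone compartments")
  seeds <- draw_subseeds(seed, 4L)
  vals <- array(0, grid$shape)
  mats <- materials[need]
  for (k in seq_along(mats)) {
    m <- mats[[k]]
    region <- labels == (k - 1L)
    vals[region] <- m$mean_intensity
    if (m$texture_sd > 0) {
      old <- if (exists(".Random.seed", .GlobalEnv))
        get(".Random.seed", .GlobalEnv) else NULL
      set.seed(seeds[k])
      fld <- texture_field(grid$shape, grid$spacing, m$texture_sd,
                           m$correlation_length, region)
      if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
      vals[region] <- vals[region] + fld[region]
    }
  }
  list(image = voxel_image(vals, spacing = grid$spacing,
                           origin = grid$origin),
       labels = labels)
}

#' Generate the digital texture phantom
#'
#' A homogeneous block (Perspex-like) with parallel cylindrical inserts of
#' differing density/texture running the full slice direction, mirroring a
#' 60 mm block with 20 mm diameter inserts.
#'
#' @param grid a [grid_spec()].
#' @param inserts named list of at least two [material_spec()]s (see
#'   [texture_inserts()]).
#' @param seed integer seed.
#' @param insert_radius cylinder radius in mm (default 10, i.e. a 20 mm
#'   insert); cylinders that would overlap or leave the block raise an error.
#' @return List with `image`, `labels` (0 block, then 1..n in insert order)
#'   and `insert_names`.
#' @export
generate_texture_phantom <- function(grid, inserts = texture_inserts(),
                                     seed = 1L, insert_radius = NULL) {
  stopifnot(inherits(grid, "grid_spec"))
  n_ins <- length(inserts)
  if (n_ins < 2L) stop("generate_texture_phantom: need at least 2 inserts")
  extent <- grid$shape * grid$spacing
  if (is.null(insert_radius))
    insert_radius <- min(10, 0.18 * min(extent[1:2]))
  # place insert axes on a ring around the block centre
  ring_r <- 0.28 * min(extent[1:2])
  ang <- 2 * pi * (seq_len(n_ins) - 1) / n_ins
  cx <- ring_r * cos(ang)
  cy <- ring_r * sin(ang)
  if (n_ins > 1) {
    min_gap <- min(stats::dist(cbind(cx, cy)))
    if (min_gap < 2 * insert_radius)
      stop("generate_texture_phantom: cylindrical inserts overlap ",
           "(centre gap ", signif(min_gap, 3), " mm < diameter ",
           2 * insert_radius, " mm)")
  }
  if (ring_r + insert_radius > min(extent[1:2]) / 2)
    stop("generate_texture_phantom: inserts do not fit inside the block")
  ax <- lapply(1:2, function(a)
    grid$origin[a] + (seq_len(grid$shape[a]) - 1) * grid$spacing[a])
  ctr <- grid$origin + (grid$shape - 1) * grid$spacing / 2
  X <- array(ax[[1]], grid$shape) - ctr[1]
  Y <- aperm(array(ax[[2]], grid$shape[c(2, 1, 3)]), c(2, 1, 3)) - ctr[2]
  labels <- array(0L, grid$shape)
  for (k in seq_len(n_ins)) {
    sel <- (X - cx[k])^2 + (Y - cy[k])^2 <= insert_radius^2
    labels[sel] <- k
  }
  block <- material_spec("perspex", 1.18, mean_intensity = 3200,
                         texture_sd = 110, correlation_length = 0.4)
  mats <- c(list(block), unname(inserts))
  seeds <- draw_subseeds(seed, length(mats))
  vals <- array(0, grid$shape)
  for (k in seq_along(mats)) {
    m <- mats[[k]]
    region <- labels == (k - 1L)
    if (!any(region)) next
    vals[region] <- m$mean_intensity
    if (m$texture_sd > 0) {
      set.seed(seeds[k])
      fld <- texture_field(grid$shape, grid$spacing, m$texture_sd,
                           m$correlation_length, region)
      vals[region] <- vals[region] + fld[region]
    }
  }
  list(image = voxel_image(vals, spacing = grid$spacing,
                           origin = grid$origin),
       labels = labels, insert_names = names(inserts))
}

#' Simulate a scan-rescan pair
#'
#' Applies protocol contrast scaling to the (noise-free) phantom and adds an
#' independent white-noise realisation plus a smooth bias field per scan.
#' The two outputs share geometry and expectation; with `noise_sd = 0` and
#' `bias_amplitude = 0` they are identical regardless of seeds.
#'
#' @param phantom a [voxel_image()] (the object; typically the `image` of a
#'   phantom generator).
#' @param protocol a [scan_protocol()].
#' @param seeds integer pair, one per scan.
#' @return List of two [voxel_image()]s (`scan`, `rescan`).
#' @export
simulate_scan_pair <- function(phantom, protocol = scan_protocol(60),
                               seeds = c(1L, 2L)) {
  stopifnot(inherits(phantom, "voxel_image"),
            inherits(protocol, "scan_protocol"))
  seeds <- as.integer(rep_len(seeds, 2L))
  one <- function(s) {
    vals <- protocol$contrast_scale * phantom$values
    if (protocol$noise_sd > 0 || protocol$bias_amplitude > 0) {
      set.seed(s)
      dm <- dim(vals)
      if (protocol$noise_sd > 0)
        vals <- vals + array(stats::rnorm(prod(dm), 0, protocol$noise_sd),
                             dm)
      if (protocol$bias_amplitude > 0) {
        bias_len <- 0.2 * min(dm * phantom$spacing)
        vals <- vals + texture_field(dm, phantom$spacing,
                                     protocol$bias_amplitude, bias_len)
      }
    }
    voxel_image(vals, spacing = phantom$spacing, origin = phantom$origin)
  }
  list(scan = one(seeds[1]), rescan = one(seeds[2]))
}

#' Cohort description for the two-arm tumour simulation
#'
#' @param name cohort label (e.g. "A549-like").
#' @param n_subjects subjects per arm (>= 2; the pilot uses 9).
#' @param tumour_volume spherical segmentation volume in mm^3 (default
#'   94.25, the standard tumour segmentation).
#' @param mean_intensity,texture_sd,correlation_length tumour texture
#'   parameters (scanner units / mm).
#' @param between_subject_sd biological heterogeneity: each subject's tumour
#'   mean intensity is drawn around `mean_intensity` with this standard
#'   deviation (scanner units).
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(name, n_subjects = 9L, tumour_volume = 94.25,
                        mean_intensity = 12000, texture_sd = 600,
                        correlation_length = 0.4,
                        between_subject_sd = 600) {
  if (n_subjects < 2L) stop("cohort_spec: n_subjects must be >= 2")
  if (!is.finite(tumour_volume) || tumour_volume <= 0)
    stop("cohort_spec: tumour_volume must be > 0")
  if (between_subject_sd < 0)
    stop("cohort_spec: between_subject_sd must be >= 0")
  structure(list(name = name, n_subjects = as.integer(n_subjects),
                 tumour_volume = tumour_volume,
                 mean_intensity = mean_intensity, texture_sd = texture_sd,
                 correlation_length = correlation_length,
                 between_subject_sd = between_subject_sd),
            class = "cohort_spec")
}

#' Two default cohorts separated by a texture effect
#'
#' Arm B's mean tumour intensity is shifted by `effect_size` texture
#' standard deviations relative to arm A; `effect_size = 0` gives two arms
#' drawn from the same distribution (the null).
#' @param effect_size separation in texture-sd units (>= 0).
#' @param n_subjects subjects per arm.
#' @return List with `A` and `B` [cohort_spec()]s.
#' @export
cohort_pair_specs <- function(effect_size = 2, n_subjects = 9L) {
  if (effect_size < 0) stop("cohort_pair_specs: effect_size must be >= 0")
  a <- cohort_spec("A549-like", n_subjects = n_subjects)
  b <- cohort_spec("H460-like", n_subjects = n_subjects,
                   mean_intensity = a$mean_intensity +
                     effect_size * a$texture_sd)
  list(A = a, B = b)
}

#' Generate a two-arm synthetic tumour cohort
#'
#' Each subject is a soft-tissue background volume with a spherical tumour
#' of the cohort's texture at the grid centre, paired with the matching
#' spherical segmentation mask.
#'
#' @param specA,specB [cohort_spec()]s for the two arms.
#' @param grid a [grid_spec()]; the tumour sphere must fit inside.
#' @param seed integer seed.
#' @return List of subjects, each `list(image, mask, cohort, subject_id)`;
#'   arm A subjects come first.
#' @export
generate_tumour_cohort <- function(specA, specB, grid, seed = 1L) {
  stopifnot(inherits(specA, "cohort_spec"), inherits(specB, "cohort_spec"),
            inherits(grid, "grid_spec"))
  extent <- grid$shape * grid$spacing
  subjects <- list()
  seeds <- draw_subseeds(seed, specA$n_subjects + specB$n_subjects)
  si <- 0L
  for (spec in list(specA, specB)) {
    r <- (3 * spec$tumour_volume / (4 * pi))^(1 / 3)
    if (2 * r >= min(extent))
      stop("generate_tumour_cohort: tumour sphere (radius ",
           signif(r, 3), " mm) does not fit the grid")
    for (j in seq_len(spec$n_subjects)) {
      si <- si + 1L
      set.seed(seeds[si])
      dm <- grid$shape
      subj_mean <- spec$mean_intensity +
        stats::rnorm(1, 0, spec$between_subject_sd)
      background <- 16800 +
        texture_field(dm, grid$spacing, 350, 0.5)
      mask <- make_spherical_mask(grid, volume = spec$tumour_volume)
      region <- mask$values == 1L
      tum <- subj_mean +
        texture_field(dm, grid$spacing, spec$texture_sd,
                      spec$correlation_length, region)
      vals <- background
      vals[region] <- tum[region]
      subjects[[si]] <- list(
        image = voxel_image(vals, spacing = grid$spacing,
                            origin = grid$origin),
        mask = mask, cohort = spec$name, subject_id = si)
    }
  }
  subjects
}
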