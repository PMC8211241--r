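# Synthetic mouse-thorax phantom: a stylized CT volume with exact labels.
#
# The phantom emulates the anatomy the segmentation pipeline assumes: a
# closed ribcage of high-density bone around an elliptical thoracic cavity,
# two lung wings separated by a soft-tissue mediastinal corridor, a heart
# ellipsoid, a bifurcating airway (one tracheal column cranially, two
# bronchi caudal of the bifurcation), a diaphragm dome capping the cavity
# caudally, an intermediate-density lining at the pleural boundary and
# around the heart, and optional spherical tumors that overwrite lung.
# Intensities are arbitrary units; only the ordering
# lung < intermediate < soft < bone matters downstream.

#' Phantom specification
#'
#' Parameters of the synthetic thorax generator. All slice indices are
#' 1-based with slice 1 most caudal. Geometry defaults scale with
#' `grid_shape` so smaller test grids stay anatomically proportioned.
#'
#' @param grid_shape integer vector (nx, ny, nz); default 160 x 160 x 120.
#' @param voxel_size_mm isotropic voxel edge, default 0.1.
#' @param tissue_means named numeric vector of mean intensities for
#'   `lung`, `intermediate`, `soft`, `bone`; must be strictly increasing in
#'   that order. Defaults 0.05 / 0.35 / 0.55 / 1.0.
#' @param noise_sd per-class Gaussian noise SD: a scalar or a named vector
#'   over the same classes. Default 0.03.
#' @param rib_count rib arcs per side per axial slice (default 4).
#' @param rib_thickness_vox radial rib thickness in voxels (default 2).
#' @param cavity_radii `nz x 2` matrix of per-slice ellipse semi-axes
#'   (a = x, b = y); `NULL` for the default linear caudal-to-cranial taper.
#' @param trachea_bifurcation_z slice where the single tracheal column
#'   splits into two bronchi (two columns at `z <= trachea_bifurcation_z`).
#' @param diaphragm_apex_z slice of the diaphragm dome apex.
#' @param dome_curvature drop (slices) of the dome surface from the apex at
#'   the cavity centre to the cavity edge.
#' @param tumors list of tumors, each `list(center = c(x, y, z),
#'   radius_vox, class = "soft"|"intermediate")`; tumors only overwrite
#'   lung voxels and grow an intermediate shell of ~2 voxels.
#' @param motion_blur_sd in-plane Gaussian blur SD (voxels) applied to the
#'   intensities only, emulating minor respiratory motion; labels are never
#'   blurred. Default 0 (off).
#' @param seed default seed used by [generate_phantom()].
#' @return A validated list of class `phantom_spec`. The attached
#'   `geometry` element holds the derived internal geometry (centre,
#'   corridor width, heart ellipsoid, lining thickness, ...).
#' @export
phantom_spec <- function(grid_shape = c(160, 160, 120),
                         voxel_size_mm = 0.1,
                         tissue_means = c(lung = 0.05, intermediate = 0.35,
                                          soft = 0.55, bone = 1.0),
                         noise_sd = 0.03,
                         rib_count = 4,
                         rib_thickness_vox = 2,
                         cavity_radii = NULL,
                         trachea_bifurcation_z = NULL,
                         diaphragm_apex_z = NULL,
                         dome_curvature = NULL,
                         tumors = list(),
                         motion_blur_sd = 0,
                         seed = 1) {
  if (length(grid_shape) != 3L || any(grid_shape < 32))
    stop("grid_shape must be 3 integers >= 32")
  nx <- as.integer(grid_shape[1]); ny <- as.integer(grid_shape[2])
  nz <- as.integer(grid_shape[3])
  classes <- c("lung", "intermediate", "soft", "bone")
  if (!all(classes %in% names(tissue_means)))
    stop("tissue_means must name lung, intermediate, soft, bone")
  tm <- tissue_means[classes]
  if (any(diff(tm) <= 0))
    stop("tissue_means must be strictly increasing: lung < intermediate < soft < bone")
  if (is.null(names(noise_sd)))
    noise_sd <- stats::setNames(rep(noise_sd[1], 4), classes)
  noise_sd <- noise_sd[classes]
  if (any(noise_sd < 0) || any(is.na(noise_sd)))
    stop("noise_sd must be nonnegative for every class")
  if (is.null(trachea_bifurcation_z)) trachea_bifurcation_z <- round(0.81 * nz)
  if (is.null(diaphragm_apex_z)) diaphragm_apex_z <- round(0.33 * nz)
  if (is.null(dome_curvature)) dome_curvature <- round(0.18 * nz)
  if (trachea_bifurcation_z <= diaphragm_apex_z)
    stop("trachea_bifurcation_z must lie cranial of diaphragm_apex_z")
  if (trachea_bifurcation_z >= nz || diaphragm_apex_z < 2)
    stop("axial landmarks must lie inside the grid")
  if (is.null(cavity_radii)) {
    t <- (seq_len(nz) - 1) / (nz - 1)
    cavity_radii <- cbind(a = 0.275 * nx * (1 - t) + 0.185 * nx * t,
                          b = 0.260 * ny * (1 - t) + 0.175 * ny * t)
  }
  cavity_radii <- as.matrix(cavity_radii)
  if (nrow(cavity_radii) != nz || ncol(cavity_radii) != 2)
    stop("cavity_radii must be an nz x 2 matrix")
  if (any(cavity_radii <= 4)) stop("cavity semi-axes must exceed 4 voxels")
  if (rib_count < 2) stop("rib_count must be >= 2")
  if (rib_thickness_vox <= 0) stop("rib_thickness_vox must be positive")
  if (motion_blur_sd < 0) stop("motion_blur_sd must be nonnegative")

  geom <- list(
    cx = nx / 2 + 0.5,
    cy = ny / 2 - 0.04 * ny,
    rib_gap = 1,                 # muscle gap between cavity and rib, voxels
    body_margin = 4,             # muscle shell outside the ribs, voxels
    z_rib_lo = max(4L, round(0.05 * nz)),
    lining_vox = 2.4,            # intermediate pleural lining thickness
    corridor_halfwidth = 0.058 * nx,
    corridor_dorsal_frac = 0.55, # corridor spans dy > -frac * b
    airway_dx = 0.031 * nx,      # bronchus x offset from midline
    airway_dy = -0.062 * ny,     # airway y offset (ventral)
    trachea_r = 0.0175 * nx,
    bronchus_r = 0.0138 * nx,
    wing_top = trachea_bifurcation_z - 6L,
    heart = list(dx = -0.05 * nx, dy = -0.03 * ny,
                 z0 = diaphragm_apex_z + round(0.22 * nz),
                 rx = 0.15 * nx, ry = 0.135 * ny, rz = round(0.18 * nz),
                 shell = 1.13),
    tumor_shell_vox = 2)
  # the whole ribcage plus body shell must fit inside the grid
  amax <- max(cavity_radii[, 1]); bmax <- max(cavity_radii[, 2])
  pad <- geom$rib_gap + rib_thickness_vox + 2.5 + geom$body_margin
  if (geom$cx - amax - pad < 1 || geom$cx + amax + pad > nx ||
      geom$cy - bmax - pad < 1 || geom$cy + bmax + pad > ny)
    stop("geometry exceeds grid: cavity plus ribcage does not fit in grid_shape")

  spec <- list(grid_shape = c(nx, ny, nz), voxel_size_mm = voxel_size_mm,
               tissue_means = tm, noise_sd = noise_sd,
               rib_count = as.integer(rib_count),
               rib_thickness_vox = rib_thickness_vox,
               cavity_radii = cavity_radii,
               trachea_bifurcation_z = as.integer(trachea_bifurcation_z),
               diaphragm_apex_z = as.integer(diaphragm_apex_z),
               dome_curvature = dome_curvature,
               tumors = tumors, motion_blur_sd = motion_blur_sd,
               seed = as.integer(seed), geometry = geom)
  class(spec) <- "phantom_spec"
  validate_tumors(spec)
  spec
}

validate_tumors <- function(spec) {
  g <- spec$geometry
  nz <- spec$grid_shape[3]
  for (i in seq_along(spec$tumors)) {
    tu <- spec$tumors[[i]]
    if (is.null(tu$center) || length(tu$center) != 3L || is.null(tu$radius_vox))
      stop("tumor ", i, " must have center = c(x, y, z) and radius_vox")
    if (!is.null(tu$class) && !tu$class %in% c("soft", "intermediate"))
      stop("tumor ", i, ": class must be 'soft' or 'intermediate'")
    ctr <- tu$center; r <- tu$radius_vox
    if (any(ctr - r < 1) || ctr[1] + r > spec$grid_shape[1] ||
        ctr[2] + r > spec$grid_shape[2] || ctr[3] + r > nz)
      stop("geometry exceeds grid: tumor ", i, " sphere leaves the volume")
    z <- round(ctr[3])
    if (z < 1 || z > nz) stop("tumor ", i, " centered outside the cavity")
    a <- spec$cavity_radii[z, 1]; b <- spec$cavity_radii[z, 2]
    e <- sqrt(((ctr[1] - g$cx) / a)^2 + ((ctr[2] - g$cy) / b)^2)
    if (e > 1) stop("tumor ", i, " centered outside the cavity")
  }
  invisible(spec)
}

# evaluate an expression under a temporary RNG seed, restoring global state
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Generate a synthetic thorax phantom
#'
#' Renders the phantom described by a [phantom_spec()] into an intensity
#' volume (per-class Gaussian noise around the class means, optional
#' in-plane motion blur) and the exact label volume. Bit-identical output
#' for identical `(spec, seed)`; different seeds change only the noise,
#' never the labels.
#'
#' Label codes follow [tissue_legend()]: outside / lung / intermediate /
#' soft / bone / diaphragm. "Outside" covers everything beyond the thoracic
#' cavity and ribcage; its rendered intensity is air except for a
#' soft-density muscle shell hugging the ribs, so bone sits in realistic
#' surroundings.
#'
#' @param spec a [phantom_spec()].
#' @param seed integer seed for the intensity noise (defaults to
#'   `spec$seed`).
#' @return `list(volume = ct_volume, labels = label_volume)`.
#' @export
generate_phantom <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "phantom_spec"))
  validate_tumors(spec)
  g <- spec$geometry
  nx <- spec$grid_shape[1]; ny <- spec$grid_shape[2]; nz <- spec$grid_shape[3]
  leg <- tissue_legend()
  labels <- array(leg[["outside"]], c(nx, ny, nz))
  # material codes drive intensity: 0 air, 1 lung, 2 intermediate, 3 soft,
  # 4 bone, 5 muscle (soft density, outside label)
  material <- array(0L, c(nx, ny, nz))

  airway <- array(FALSE, c(nx, ny, nz))
  xg <- matrix(seq_len(nx), nx, ny)
  yg <- matrix(seq_len(ny), nx, ny, byrow = TRUE)
  dx <- xg - g$cx; dy <- yg - g$cy
  thick <- spec$rib_thickness_vox

  # diaphragm dome surface per column, using the apex-slice cavity ellipse
  az <- spec$cavity_radii[spec$diaphragm_apex_z, 1]
  bz <- spec$cavity_radii[spec$diaphragm_apex_z, 2]
  e_apex <- sqrt((dx / az)^2 + (dy / bz)^2)
  dome_z <- spec$diaphragm_apex_z - spec$dome_curvature * pmin(e_apex, 1)^2

  # rib arc sectors: spine sector dorsal (+y, 90 deg), arcs fill the rest
  m <- 2L * spec$rib_count
  spine_lo <- 80; spine_hi <- 100
  span <- 360 - (spine_hi - spine_lo)
  sect_w <- span / m
  arc_frac <- 0.70
  starts <- spine_hi + (seq_len(m) - 1) * sect_w
  gaps_lo <- c(spine_lo, starts + sect_w * (0.5 + arc_frac / 2))
  gaps_hi <- c(spine_hi, starts + sect_w * (1.5 - arc_frac / 2))
  n_gaps <- length(gaps_lo)
  hrt <- g$heart

  for (z in seq_len(nz)) {
    a <- spec$cavity_radii[z, 1]; b <- spec$cavity_radii[z, 2]
    bmin <- min(a, b)
    e <- sqrt((dx / a)^2 + (dy / b)^2)
    d <- (e - 1) * bmin                       # ~radial distance outside cavity
    inside <- e <= 1
    lab <- matrix(leg[["outside"]], nx, ny)
    mat <- matrix(0L, nx, ny)

    mat[d > 0 & d <= g$rib_gap + thick + 2.5 + g$body_margin] <- 5L  # muscle

    if (z >= g$z_rib_lo) {
      theta <- (atan2(dy / b, dx / a) * 180 / pi) %% 360
      annul <- d > g$rib_gap & d <= g$rib_gap + thick
      spine <- d > g$rib_gap & d <= g$rib_gap + thick + 2.5 &
        theta >= spine_lo & theta <= spine_hi
      bone <- spine
      for (k in seq_len(m)) {
        lo <- starts[k] + sect_w * (0.5 - arc_frac / 2)
        hi <- starts[k] + sect_w * (0.5 + arc_frac / 2)
        th <- theta
        if (hi > 360) th <- ifelse(theta < lo - 180, theta + 360, theta)
        bone <- bone | (annul & th >= lo & th <= hi)
      }
      # every 3rd slice closes one intercostal gap so the ribcage is a
      # single 3D connected component while typical slices keep
      # 2 * rib_count + 1 separate bone regions
      if ((z - g$z_rib_lo) %% 3 == 0) {
        gk <- ((z - g$z_rib_lo) %/% 3) %% n_gaps + 1
        lo <- gaps_lo[gk]; hi <- gaps_hi[gk]
        th <- theta
        if (hi > 360) th <- ifelse(theta < lo - 180, theta + 360, theta)
        bone <- bone | (annul & th >= lo - 1 & th <= hi + 1)
      }
      lab[bone] <- leg[["bone"]]
      mat[bone] <- 4L
    }

    dia <- inside & z <= dome_z
    above <- inside & !dia
    lining <- above & (1 - e) * bmin <= g$lining_vox
    # the mediastinal corridor widens cranially, so the lung fraction of
    # the cavity peaks just above the diaphragm dome apex as in vivo
    wz <- g$corridor_halfwidth *
      (1 + 1.1 * max(0, z - spec$diaphragm_apex_z) /
         (nz - spec$diaphragm_apex_z))
    corridor <- above & !lining & abs(dx) < wz &
      dy > -g$corridor_dorsal_frac * b
    wings <- above & !lining & !corridor
    lab[dia] <- leg[["diaphragm"]]; mat[dia] <- 3L
    lab[lining] <- leg[["intermediate"]]; mat[lining] <- 2L
    lab[corridor] <- leg[["soft"]]; mat[corridor] <- 3L
    if (z <= g$wing_top) {
      lab[wings] <- leg[["lung"]]; mat[wings] <- 1L
    } else {
      lab[wings] <- leg[["soft"]]; mat[wings] <- 3L
    }

    # heart ellipsoid with an intermediate shell where it borders lung
    he <- ((dx - hrt$dx) / hrt$rx)^2 + ((dy - hrt$dy) / hrt$ry)^2 +
      ((z - hrt$z0) / hrt$rz)^2
    shell <- above & he > 1 & he <= hrt$shell^2 & lab == leg[["lung"]]
    core <- above & he <= 1
    lab[shell] <- leg[["intermediate"]]; mat[shell] <- 2L
    lab[core] <- leg[["soft"]]; mat[core] <- 3L

    # airway: one tracheal column cranial of the bifurcation, two bronchi
    # at and below it (down to the top of the heart)
    ay <- dy - g$airway_dy
    aw <- matrix(FALSE, nx, ny)
    if (z > spec$trachea_bifurcation_z) {
      aw <- inside & dx^2 + ay^2 <= g$trachea_r^2
    } else if (z > hrt$z0 + hrt$rz - 2) {
      aw <- inside & (((dx - g$airway_dx)^2 + ay^2 <= g$bronchus_r^2) |
                        ((dx + g$airway_dx)^2 + ay^2 <= g$bronchus_r^2))
    }
    lab[aw] <- leg[["lung"]]; mat[aw] <- 1L

    labels[, , z] <- lab
    material[, , z] <- mat
    airway[, , z] <- aw
  }

  # tumors overwrite lung voxels only, with an intermediate shell
  if (length(spec$tumors)) {
    zc <- array(rep(seq_len(nz), each = nx * ny), c(nx, ny, nz))
    dx3 <- array(dx, c(nx, ny, nz)); dy3 <- array(dy, c(nx, ny, nz))
    for (tu in spec$tumors) {
      cls <- if (is.null(tu$class)) "soft" else tu$class
      dist2 <- (dx3 - (tu$center[1] - g$cx))^2 +
        (dy3 - (tu$center[2] - g$cy))^2 + (zc - tu$center[3])^2
      core <- dist2 <= tu$radius_vox^2 & labels == leg[["lung"]]
      sh <- dist2 > tu$radius_vox^2 &
        dist2 <= (tu$radius_vox + g$tumor_shell_vox)^2 &
        labels == leg[["lung"]]
      labels[core] <- leg[[cls]]
      material[core] <- if (cls == "soft") 3L else 2L
      labels[sh] <- leg[["intermediate"]]; material[sh] <- 2L
    }
    # airway lumens stay air-filled regardless of surrounding tumor
    labels[airway] <- leg[["lung"]]; material[airway] <- 1L
  }

  means <- c(0, spec$tissue_means[c("lung", "intermediate", "soft", "bone")],
             spec$tissue_means[["soft"]])
  sds <- c(min(spec$noise_sd) / 3, spec$noise_sd[c("lung", "intermediate",
                                                   "soft", "bone")],
           spec$noise_sd[["soft"]])
  intens <- with_local_seed(seed, {
    v <- means[material + 1L] + rnorm(length(material)) * sds[material + 1L]
    array(v, dim(material))
  })
  if (spec$motion_blur_sd > 0) {
    for (z in seq_len(nz))
      intens[, , z] <- EBImage::gblur(intens[, , z],
                                      sigma = spec$motion_blur_sd)
  }
  list(volume = ct_volume(intens, spec$voxel_size_mm),
       labels = label_volume(labels, leg, spec$voxel_size_mm))
}

#' Place a spherical tumor inside a lung wing
#'
#' Convenience constructor for the `tumors` field of [phantom_spec()]: a
#' sphere centred mid-wing (between the mediastinal corridor and the
#' pleural lining), at a chosen height between the diaphragm dome apex and
#' the top of the lung field. Tumors only ever overwrite lung voxels, so a
#' radius larger than the wing simply saturates.
#'
#' @param spec a [phantom_spec()] providing the geometry.
#' @param radius_vox tumor radius in voxels.
#' @param side `"left"` or `"right"` wing.
#' @param frac_z vertical position as a fraction of the span from dome
#'   apex to the top of the lung field (default 0.5 = mid-lung).
#' @param class tumor density class, `"soft"` (default) or
#'   `"intermediate"`.
#' @return A tumor list suitable for `phantom_spec(tumors = list(...))`.
#' @export
wing_tumor <- function(spec, radius_vox, side = c("left", "right"),
                       frac_z = 0.5, class = "soft") {
  stopifnot(inherits(spec, "phantom_spec"))
  side <- match.arg(side)
  g <- spec$geometry
  z <- round(spec$diaphragm_apex_z +
               frac_z * (g$wing_top - spec$diaphragm_apex_z))
  a <- spec$cavity_radii[z, 1]
  sgn <- if (side == "left") -1 else 1
  x <- g$cx + sgn * (g$corridor_halfwidth + a - g$lining_vox) / 2
  list(center = c(x, g$cy, z), radius_vox = radius_vox, class = class)
}

#' Ground-truth tissue fractions of a phantom
#'
#' Percentages of lung / intermediate / soft voxels within the true
#' thoracic cavity of a label volume, restricted to slices at or caudal of
#' the cranial bound, excluding diaphragm, bone and outside voxels. The
#' three percentages sum to 100 exactly (to within 1e-9).
#'
#' @param labels a [label_volume()].
#' @param bounds an `axial_bounds` object (see [cranial_cutoff()]), or a
#'   list with element `z_cranial`.
#' @return Named numeric vector `c(pct_lung, pct_intermediate, pct_soft)`.
#' @export
ground_truth_fractions <- function(labels, bounds) {
  stopifnot(inherits(labels, "label_volume"))
  nz <- dim(labels$labels)[3]
  zc <- bounds$z_cranial
  if (is.null(zc) || zc < 1 || zc > nz)
    stop("bounds z_cranial outside volume z range [1, ", nz, "]")
  leg <- labels$legend
  sub <- labels$labels[, , seq_len(zc)]
  n_lung <- sum(sub == leg[["lung"]])
  n_int <- sum(sub == leg[["intermediate"]])
  n_soft <- sum(sub == leg[["soft"]])
  tot <- n_lung + n_int + n_soft
  if (tot == 0) stop("no cavity tissue voxels within bounds")
  100 * c(pct_lung = n_lung, pct_intermediate = n_int, pct_soft = n_soft) / tot
}
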