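# Thoracic cavity masking from the ribcage.
#
# The cavity is delineated slice-by-slice from the bones: threshold the
# volume for high-density bone, keep the largest 3D connected object,
# stack neighbouring slices to smooth rib transitions, find per-slice bone
# regions (ribs, spine), pool their innermost boundary points, order them
# clockwise about a centroid and join them with a closed periodic spline.
# A second pass recentres on the first mask and keeps only the innermost
# 30% of rib points, which stabilizes the outline on scans with minor
# motion artifact and keeps intercostal muscle out of the cavity.

#' Threshold high-density bone
#'
#' @param v a [ct_volume()].
#' @param bone_threshold numeric threshold, or `"auto"` for a two-stage
#'   Otsu rule: a first Otsu threshold on the intensities above the volume
#'   median separates tissue from the air-dominated background, and a
#'   second Otsu pass on the voxels above that split isolates the bimodal
#'   bone/soft transition. No calibrated units are assumed.
#' @return A `bone_mask`: list with logical array `mask`, the `threshold`
#'   used and (once labeled) the `connectivity`.
#' @export
threshold_bone <- function(v, bone_threshold = "auto") {
  stopifnot(inherits(v, "ct_volume"))
  x <- v$intensities
  if (identical(bone_threshold, "auto")) {
    otsu_on <- function(vals) {
      rng <- range(vals)
      if (diff(rng) <= 0) stop("no bone voxels above threshold: flat volume")
      thr <- EBImage::otsu(EBImage::Image((vals - rng[1]) / diff(rng)),
                           range = c(0, 1), levels = 256L)
      rng[1] + thr * diff(rng)
    }
    t1 <- otsu_on(x[x > median(x)])
    bone_threshold <- otsu_on(x[x > t1])
  }
  m <- x >= bone_threshold
  if (!any(m)) stop("no bone voxels above threshold ", signif(bone_threshold, 4))
  structure(list(mask = m, threshold = bone_threshold, connectivity = NA),
            class = "bone_mask")
}

#' Keep the largest 3D connected component of a bone mask
#'
#' Ties in component size are broken toward the component containing the
#' voxel with the smallest linear index.
#'
#' @param m a `bone_mask` from [threshold_bone()].
#' @param connectivity 6, 18 or 26.
#' @return A `bone_mask` retaining only the largest component.
#' @export
largest_component_3d <- function(m, connectivity = 26) {
  stopifnot(inherits(m, "bone_mask"))
  if (!any(m$mask)) stop("empty bone mask")
  lab <- .cc_label(as.vector(m$mask), dim(m$mask), as.integer(connectivity))
  sizes <- tabulate(lab[lab > 0L])
  keep <- which.max(sizes)  # first max = smallest first linear index
  m$mask <- array(lab == keep, dim(m$mask))
  m$connectivity <- connectivity
  m
}

#' Stack axial slices of a bone mask
#'
#' Each output slice is the voxelwise union of the `window` input slices
#' centred on it (clamped at the volume ends), smoothing the slice-to-slice
#' transition of obliquely-running ribs.
#'
#' @param m a `bone_mask`.
#' @param window odd positive integer (default 3).
#' @return A `bone_mask` with the stacked mask.
#' @export
stack_slices <- function(m, window = 3) {
  stopifnot(inherits(m, "bone_mask"))
  if (window %% 2 != 1 || window < 1) stop("window must be a positive odd integer")
  nz <- dim(m$mask)[3]
  if (window > nz) stop("window exceeds number of slices")
  if (window == 1) return(m)
  h <- (window - 1) / 2
  out <- m$mask
  for (off in seq(-h, h)) {
    if (off == 0) next
    zi <- pmin(pmax(seq_len(nz) + off, 1L), nz)
    out <- out | m$mask[, , zi, drop = FALSE]
  }
  m$mask <- out
  m
}

# boundary pixels of labeled 2D regions: pixels with a 4-neighbour of a
# different label (or at the image edge)
boundary_pixels <- function(lab) {
  nx <- nrow(lab); ny <- ncol(lab)
  pad <- matrix(0L, nx + 2, ny + 2)
  pad[2:(nx + 1), 2:(ny + 1)] <- lab
  ctr <- pad[2:(nx + 1), 2:(ny + 1)]
  b <- ctr > 0L & (pad[1:nx, 2:(ny + 1)] != ctr |
                     pad[3:(nx + 2), 2:(ny + 1)] != ctr |
                     pad[2:(nx + 1), 1:ny] != ctr |
                     pad[2:(nx + 1), 3:(ny + 2)] != ctr)
  which(b, arr.ind = TRUE)
}

#' Identify rib/spine regions in one axial slice
#'
#' 8-connected components of the (stacked) bone slice with at least
#' `min_region_px` pixels, each with its area, centroid and boundary pixel
#' list.
#'
#' @param slice_mask logical 2D matrix.
#' @param min_region_px minimum region area in pixels (default 3).
#' @return List of regions, each `list(area, centroid = c(x, y),
#'   boundary = n x 2 matrix)`; empty list when no region qualifies.
#' @export
rib_regions <- function(slice_mask, min_region_px = 3) {
  stopifnot(is.matrix(slice_mask))
  if (!any(slice_mask)) return(list())
  lab <- .cc_label(as.vector(slice_mask), dim(slice_mask), 8L)
  ncomp <- attr(lab, "n_components")
  sizes <- tabulate(lab[lab > 0L], nbins = ncomp)
  keep <- which(sizes >= min_region_px)
  if (!length(keep)) return(list())
  bnd <- boundary_pixels(lab)
  bnd_lab <- lab[bnd]
  idx <- which(lab > 0L, arr.ind = TRUE)
  idx_lab <- lab[idx]
  lapply(keep, function(k) {
    px <- idx[idx_lab == k, , drop = FALSE]
    list(area = sizes[k],
         centroid = c(mean(px[, 1]), mean(px[, 2])),
         boundary = unname(bnd[bnd_lab == k, , drop = FALSE]))
  })
}

#' Innermost rib points
#'
#' Pools the boundary pixels of all regions and returns the fraction
#' closest to `center` by Euclidean distance. `fraction = 1` (the first
#' mask pass) returns the whole pool; the second pass uses 0.3.
#'
#' @param regions list from [rib_regions()].
#' @param center numeric `c(x, y)` reference point.
#' @param fraction scalar in (0, 1].
#' @return `n x 2` matrix of points, closest first.
#' @export
innermost_points <- function(regions, center, fraction = 1) {
  if (!length(regions)) stop("no rib regions to pool points from")
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  pts <- do.call(rbind, lapply(regions, `[[`, "boundary"))
  if (is.null(pts) || !nrow(pts)) stop("empty boundary point pool")
  d <- sqrt((pts[, 1] - center[1])^2 + (pts[, 2] - center[2])^2)
  ord <- order(d, pts[, 1], pts[, 2])
  pts[ord[seq_len(ceiling(fraction * nrow(pts)))], , drop = FALSE]
}

#' Order points clockwise about a centre
#'
#' Points are sorted by decreasing mathematical angle `atan2(y - cy,
#' x - cx)`, starting at angle pi (the -x direction); angle ties are broken
#' by increasing radius. With the x-y axial plane viewed conventionally
#' this is a clockwise traversal, and the cyclic order is reproducible.
#'
#' @param points `n x 2` matrix (n >= 3).
#' @param center numeric `c(x, y)`.
#' @return The reordered points matrix.
#' @export
clockwise_order <- function(points, center) {
  if (nrow(points) < 3) stop("need at least 3 points")
  dx <- points[, 1] - center[1]; dy <- points[, 2] - center[2]
  r <- sqrt(dx^2 + dy^2)
  if (all(r < 1e-12)) stop("all points coincide with the centre")
  ang <- atan2(dy, dx)
  key <- (pi - ang) %% (2 * pi)   # 0 at angle pi, increasing clockwise
  points[order(key, r), , drop = FALSE]
}

# even-odd scanline fill of a closed polygon: marks pixels whose centres
# lie inside the curve, which keeps the rasterized area unbiased
fill_contour <- function(xs, ys, shape) {
  xs <- pmin(pmax(xs, 0.5), shape[1] + 0.5)
  ys <- pmin(pmax(ys, 0.5), shape[2] + 0.5)
  n <- length(xs)
  if (xs[1] != xs[n] || ys[1] != ys[n]) { xs <- c(xs, xs[1]); ys <- c(ys, ys[1]) }
  x1 <- xs[-length(xs)]; x2 <- xs[-1]
  y1 <- ys[-length(ys)]; y2 <- ys[-1]
  keep <- y1 != y2
  x1 <- x1[keep]; x2 <- x2[keep]; y1 <- y1[keep]; y2 <- y2[keep]
  m <- matrix(FALSE, shape[1], shape[2])
  for (y0 in seq_len(shape[2])) {
    cr <- (y1 <= y0) != (y2 <= y0)
    if (!any(cr)) next
    xc <- sort(x1[cr] + (y0 - y1[cr]) * (x2[cr] - x1[cr]) / (y2[cr] - y1[cr]))
    nc <- length(xc) - length(xc) %% 2
    for (i in seq(1, nc, by = 2)) {
      lo <- floor(xc[i]) + 1L
      hi <- ceiling(xc[i + 1]) - 1L
      if (hi >= lo) m[max(lo, 1L):min(hi, shape[1]), y0] <- TRUE
    }
  }
  m
}

shoelace_area <- function(xs, ys) {
  n <- length(xs)
  abs(sum(xs * ys[c(2:n, 1)] - xs[c(2:n, 1)] * ys)) / 2
}

#' Closed spline outline of ordered points, filled
#'
#' Fits a closed periodic cubic spline through the ordered control points,
#' samples it densely (at least 4x the point count), rasterizes the closed
#' contour and fills its interior. A sampled contour that fails to enclose
#' its own polygon area (self-intersection / degeneracy) falls back to the
#' filled polygon of the control points, with a message.
#'
#' @param points ordered `n x 2` matrix, n >= 4 (see [clockwise_order()]).
#' @param slice_shape integer `c(nx, ny)` of the target slice.
#' @return Logical `nx x ny` matrix: the filled outline, clipped to the
#'   slice.
#' @export
spline_outline <- function(points, slice_shape) {
  if (nrow(points) < 4) stop("need at least 4 ordered points for a spline outline")
  n <- nrow(points)
  t <- seq_len(n + 1L) - 1L
  xs <- c(points[, 1], points[1, 1])
  ys <- c(points[, 2], points[1, 2])
  n_samp <- max(4L * n, 720L)
  tt <- seq(0, n, length.out = n_samp + 1L)
  sx <- spline(t, xs, method = "periodic", xout = tt)$y
  sy <- spline(t, ys, method = "periodic", xout = tt)$y
  filled <- fill_contour(sx, sy, slice_shape)
  poly_area <- shoelace_area(points[, 1], points[, 2])
  if (sum(filled) < 0.5 * poly_area) {
    message("spline contour degenerate; falling back to control-point polygon")
    filled <- fill_contour(xs, ys, slice_shape)
  }
  filled
}

#' Build the two-pass thoracic cavity mask
#'
#' Per axial slice, pass 1 uses all rib-outline points about the
#' whole-ribcage centroid to draw an initial cavity mask; the centroid of
#' that mask then seeds pass 2, which uses only the innermost
#' `refine_fraction` (default 30%) of the pooled rib points. The refined
#' mask is intersected with the pass-1 mask (refinement never grows the
#' cavity into the intercostal muscle) and bone voxels are removed. Slices
#' with fewer than `min_regions` rib regions inherit the nearest nonempty
#' slice's mask when within 2 slices, otherwise stay empty.
#'
#' @param v a [ct_volume()].
#' @param cfg a [pipeline_config()].
#' @return A `thoracic_mask`: list with logical array `mask`, the bone
#'   mask used, per-slice `centroids` (n x 2), per-slice `n_regions`, and
#'   the slice indices that required inheritance or stayed empty.
#' @export
build_thoracic_mask <- function(v, cfg = pipeline_config()) {
  stopifnot(inherits(v, "ct_volume"))
  bone <- threshold_bone(v, cfg$bone_threshold)
  bone <- largest_component_3d(bone, cfg$connectivity)
  stacked <- stack_slices(bone, cfg$stack_window)
  d <- dim(v$intensities)
  nz <- d[3]

  idx <- which(stacked$mask, arr.ind = TRUE)
  center_global <- c(mean(idx[, 1]), mean(idx[, 2]))

  mask <- array(FALSE, d)
  centroids <- matrix(NA_real_, nz, 2)
  n_regions <- integer(nz)
  pass1_area <- pass2_area <- rep(NA_real_, nz)
  for (z in seq_len(nz)) {
    regions <- rib_regions(stacked$mask[, , z], cfg$min_region_px)
    n_regions[z] <- length(regions)
    if (length(regions) < cfg$min_regions) next
    p1 <- clockwise_order(innermost_points(regions, center_global, 1),
                          center_global)
    m1 <- spline_outline(p1, d[1:2])
    if (!any(m1)) next
    pass1_area[z] <- sum(m1)
    ij <- which(m1, arr.ind = TRUE)
    c2 <- c(mean(ij[, 1]), mean(ij[, 2]))
    p2 <- clockwise_order(innermost_points(regions, c2, cfg$refine_fraction), c2)
    m2 <- if (nrow(p2) >= 4) spline_outline(p2, d[1:2]) & m1 else m1
    pass2_area[z] <- sum(m2)
    m2 <- m2 & !bone$mask[, , z]
    mask[, , z] <- m2
    if (any(m2)) {
      ij2 <- which(m2, arr.ind = TRUE)
      centroids[z, ] <- c(mean(ij2[, 1]), mean(ij2[, 2]))
    }
  }

  nonempty <- which(apply(mask, 3, any))
  if (length(nonempty) < 3) stop("ribcage not found: fewer than 3 slices masked")
  inherited <- integer(0)
  for (z in setdiff(seq_len(nz), nonempty)) {
    near <- nonempty[which.min(abs(nonempty - z))]
    if (abs(near - z) <= 2) {
      mask[, , z] <- mask[, , near] & !bone$mask[, , z]
      centroids[z, ] <- centroids[near, ]
      inherited <- c(inherited, z)
    }
  }
  structure(list(mask = mask, bone = bone, centroids = centroids,
                 n_regions = n_regions, pass1_area = pass1_area,
                 pass2_area = pass2_area, inherited_slices = inherited),
            class = "thoracic_mask")
}
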