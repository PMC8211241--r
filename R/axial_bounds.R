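# sum of the 8 neighbours of each cell (zero-padded edges)
shift_sum <- function(m) {
  nx <- nrow(m); ny <- ncol(m)
  p <- matrix(0, nx + 2, ny + 2)
  p[2:(nx + 1), 2:(ny + 1)] <- m
  p[1:nx, 1:ny] + p[1:nx, 2:(ny + 1)] + p[1:nx, 3:(ny + 2)] +
    p[2:(nx + 1), 1:ny] + p[2:(nx + 1), 3:(ny + 2)] +
    p[3:(nx + 2), 1:ny] + p[3:(nx + 2), 2:(ny + 1)] + p[3:(nx + 2), 3:(ny + 2)]
}

# Axial analysis bounds: cranial cutoff at the tracheal bifurcation,
# heart-diaphragm interface at the maximum-lung slice, and diaphragm
# segmentation by per-column intensity inflection.

#' Axial bounds container
#'
#' @param z_cranial slice index of the tracheal bifurcation (inclusive
#'   upper bound of the analysed volume).
#' @param z_interface slice index of the heart-diaphragm interface.
#' @param z_caudal most caudal analysed slice (default 1).
#' @return An `axial_bounds` object.
#' @export
axial_bounds <- function(z_cranial, z_interface, z_caudal = 1L) {
  if (!(z_caudal <= z_interface && z_interface < z_cranial))
    stop("bounds must satisfy z_caudal <= z_interface < z_cranial")
  structure(list(z_cranial = as.integer(z_cranial),
                 z_interface = as.integer(z_interface),
                 z_caudal = as.integer(z_caudal),
                 n_slices_used = as.integer(z_cranial - z_caudal + 1L)),
            class = "axial_bounds")
}

#' Cranial cutoff at the tracheal bifurcation
#'
#' Scanning from the cranial end caudally through the cranial-most 25% of
#' slices, the tracheal structure is taken as the lung-class 2D connected
#' components nearest the slice's mask centroid (component centroid within
#' half the mask's equivalent radius). The most cranial slice at which
#' that structure consists of two disjoint components, each at least
#' `min_airway_px` pixels, is the cutoff; slices cranial of it are
#' excluded downstream. Restricting the search to the cranial quarter
#' avoids mistaking paired structures deep in the lung for the
#' bifurcation.
#'
#' @param seg a `tissue_segmentation` from [classify_tissue()].
#' @param mask the `thoracic_mask` the segmentation was built on.
#' @param min_airway_px minimum airway component area (default 4).
#' @return Integer slice index.
#' @export
cranial_cutoff <- function(seg, mask, min_airway_px = 4) {
  stopifnot(inherits(seg, "tissue_segmentation"))
  m <- if (inherits(mask, "thoracic_mask")) mask$mask else mask
  check_same_grid(seg$classes, m, "segmentation and mask")
  nz <- dim(m)[3]
  z_lo <- ceiling(0.75 * nz)
  for (z in seq(nz, z_lo)) {
    msl <- m[, , z]
    if (!any(msl)) next
    ij <- which(msl, arr.ind = TRUE)
    ctr <- c(mean(ij[, 1]), mean(ij[, 2]))
    r_eq <- sqrt(sum(msl) / pi)
    lungm <- seg$classes[, , z] == 1L & msl
    if (!any(lungm)) next
    lab <- .cc_label(as.vector(lungm), dim(lungm), 8L)
    ncomp <- attr(lab, "n_components")
    if (ncomp < 2) next
    sizes <- tabulate(lab[lab > 0L], nbins = ncomp)
    near <- 0L
    for (k in seq_len(ncomp)) {
      if (sizes[k] < min_airway_px) next
      px <- which(lab == k, arr.ind = TRUE)
      cd <- sqrt((mean(px[, 1]) - ctr[1])^2 + (mean(px[, 2]) - ctr[2])^2)
      if (cd <= 0.5 * r_eq) near <- near + 1L
    }
    if (near == 2L) return(z)
  }
  stop("tracheal bifurcation not detected; set z_cranial in the ",
       "configuration to force a cutoff")
}

#' Heart-diaphragm interface slice
#'
#' The axial slice where the thoracic cavity contains the highest
#' percentage of lung-class voxels; ties go to the most caudal slice.
#'
#' @param seg a `tissue_segmentation`.
#' @param mask the `thoracic_mask`.
#' @return Integer slice index.
#' @export
heart_diaphragm_interface <- function(seg, mask) {
  stopifnot(inherits(seg, "tissue_segmentation"))
  m <- if (inherits(mask, "thoracic_mask")) mask$mask else mask
  check_same_grid(seg$classes, m, "segmentation and mask")
  nmask <- apply(m, 3, sum)
  if (all(nmask == 0)) stop("all slices have an empty mask")
  nlung <- apply(seg$classes == 1L & m, 3, sum)
  frac <- ifelse(nmask > 0, nlung / nmask, -Inf)
  which.max(frac)  # first maximum = most caudal
}

#' Segment the diaphragm by per-column intensity inflection
#'
#' For each in-mask (x, y) column, the intensity z-trace from the caudal
#' scan end up to the heart-diaphragm interface is smoothed with a
#' centred moving average (`smoothing_window` slices, edge-padded) and the
#' inflection is located at the steepest descending gradient, where the
#' column crosses from the dense diaphragm/abdomen into air-filled lung.
#' Voxels caudal of the inflection are labeled diaphragm. Columns whose
#' trace dynamic range is below noise (range < 2 * MAD) or never descends
#' carry no inflection of their own; because the diaphragm is a connected
#' 3D surface, such columns (typically the mediastinum, where dense tissue
#' sits both above and below the dome) receive the inflection height
#' interpolated from their nearest resolvable neighbours by iterative
#' 8-neighbour averaging. Columns outside the thoracic mask are never
#' labeled.
#'
#' @param v a [ct_volume()].
#' @param mask the `thoracic_mask`.
#' @param z_interface interface slice from [heart_diaphragm_interface()].
#' @param smoothing_window odd moving-average window (default 5).
#' @return A `diaphragm_mask`: list with logical array `mask` (a subset of
#'   the thoracic mask, empty above `z_interface`) and `z_interface`.
#' @export
segment_diaphragm <- function(v, mask, z_interface, smoothing_window = 5) {
  stopifnot(inherits(v, "ct_volume"))
  m <- if (inherits(mask, "thoracic_mask")) mask$mask else mask
  check_same_grid(v$intensities, m, "volume and mask")
  d <- dim(m)
  out <- array(FALSE, d)
  if (z_interface <= 1) {
    warning("z_interface at the caudal end; empty diaphragm mask")
    return(structure(list(mask = out, z_interface = z_interface),
                     class = "diaphragm_mask"))
  }
  zr <- seq_len(z_interface)
  colmask <- apply(m[, , zr, drop = FALSE], c(1, 2), any)
  cols <- which(colmask, arr.ind = TRUE)
  if (!nrow(cols))
    return(structure(list(mask = out, z_interface = z_interface),
                     class = "diaphragm_mask"))
  # traces matrix: rows = z, columns = (x, y) columns
  tr <- vapply(zr, function(z) v$intensities[, , z][cols], numeric(nrow(cols)))
  tr <- t(tr)
  h <- (smoothing_window - 1) / 2
  if (h > 0 && nrow(tr) > smoothing_window) {
    padded <- rbind(tr[rep(1L, h), , drop = FALSE], tr,
                    tr[rep(nrow(tr), h), , drop = FALSE])
    sm <- stats::filter(padded, rep(1 / smoothing_window, smoothing_window))
    sm <- sm[(h + 1):(h + nrow(tr)), , drop = FALSE]
  } else sm <- tr
  grad <- diff(sm)
  steep <- apply(grad, 2, which.min)
  gmin <- grad[cbind(steep, seq_len(ncol(grad)))]
  rng <- apply(sm, 2, function(x) diff(range(x)))
  mads <- apply(sm, 2, mad)
  # a column carries its own inflection only if the trace truly descends:
  # the smoothed drop across the candidate inflection must clear 4x the
  # robust per-sample noise (MAD of the differenced raw trace), on top of
  # the dynamic-range floor; flat traces otherwise pass the range test by
  # chance and would scatter spurious inflections
  nzr <- nrow(sm)
  sigma <- apply(tr, 2, function(x) mad(diff(x)) / sqrt(2))
  drop <- vapply(seq_len(ncol(sm)), function(j) {
    zi <- steep[j]
    mean(sm[seq_len(zi), j]) - mean(sm[seq(min(zi + 1L, nzr), nzr), j])
  }, numeric(1))
  usable <- gmin < 0 & rng >= 2 * mads & drop >= 4 * sigma
  # inflection height surface; complete unresolvable columns from their
  # resolvable neighbours so the dome is closed across the mediastinum
  zsurf <- matrix(NA_real_, d[1], d[2])
  zsurf[cols[usable, , drop = FALSE]] <- steep[usable]
  need <- matrix(FALSE, d[1], d[2])
  need[cols[!usable, , drop = FALSE]] <- TRUE
  it <- 0L
  while (any(need) && it < max(d[1:2])) {
    it <- it + 1L
    filled <- !is.na(zsurf)
    cnt <- shift_sum(filled)
    tot <- shift_sum(ifelse(filled, zsurf, 0))
    grow <- need & cnt > 0
    if (!any(grow)) break
    zsurf[grow] <- tot[grow] / cnt[grow]
    need[grow] <- FALSE
  }
  fill_cols <- which(!is.na(zsurf), arr.ind = TRUE)
  fill_cols <- fill_cols[colmask[fill_cols], , drop = FALSE]
  zi <- pmin(pmax(round(zsurf[fill_cols]), 0L), z_interface)
  for (j in seq_len(nrow(fill_cols))) {
    if (zi[j] >= 1L)
      out[fill_cols[j, 1], fill_cols[j, 2], seq_len(zi[j])] <- TRUE
  }
  out <- out & m
  structure(list(mask = out, z_interface = as.integer(z_interface)),
            class = "diaphragm_mask")
}

#' Apply axial bounds and diaphragm removal to a segmentation
#'
#' Voxels cranial of the bifurcation cutoff and all diaphragm voxels are
#' relabeled `outside`; the remaining class counts define the reported
#' thoracic cavity.
#'
#' @param seg a `tissue_segmentation`.
#' @param bounds an [axial_bounds()].
#' @param d a `diaphragm_mask` (or `NULL` for none).
#' @return The trimmed `tissue_segmentation` with `bounds` attached.
#' @export
apply_bounds <- function(seg, bounds, d = NULL) {
  stopifnot(inherits(seg, "tissue_segmentation"))
  nz <- dim(seg$classes)[3]
  if (bounds$z_cranial < nz)
    seg$classes[, , (bounds$z_cranial + 1L):nz] <- 0L
  if (bounds$z_caudal > 1L)
    seg$classes[, , seq_len(bounds$z_caudal - 1L)] <- 0L
  if (!is.null(d)) {
    check_same_grid(seg$classes, d$mask, "segmentation and diaphragm")
    seg$classes[d$mask] <- 0L
  }
  seg$bounds <- bounds
  seg
}
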