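#' CT volume container
#'
#' A `ct_volume` wraps a 3D scalar intensity grid with its isotropic voxel
#' spacing and the package's axis convention (x-y axial plane, slice `z = 1`
#' most caudal, z increasing cranially). Intensities are stored as doubles.
#'
#' @param intensities numeric 3D array of voxel intensities (arbitrary
#'   units; only the density ordering matters downstream).
#' @param voxel_size_mm positive scalar, isotropic voxel edge length in mm.
#' @return An object of class `ct_volume` with elements `intensities`,
#'   `voxel_size_mm` and `axis` (always `"caudocranial"`).
#' @examples
#' v <- ct_volume(array(0.5, c(16, 16, 8)), voxel_size_mm = 0.1)
#' dim(v$intensities)
#' @export
ct_volume <- function(intensities, voxel_size_mm = 0.1) {
  if (!is.array(intensities) || length(dim(intensities)) != 3L)
    stop("expected 3 dimensions, got ", length(dim(intensities)))
  if (dim(intensities)[3] < 8L)
    stop("volume must have at least 8 axial slices")
  if (!all(is.finite(intensities)))
    stop("intensities must be finite")
  if (!is.numeric(voxel_size_mm) || length(voxel_size_mm) != 1L ||
      !is.finite(voxel_size_mm) || voxel_size_mm <= 0)
    stop("voxel_size_mm must be a positive scalar")
  storage.mode(intensities) <- "double"
  structure(
    list(intensities = intensities,
         voxel_size_mm = as.numeric(voxel_size_mm),
         axis = "caudocranial"),
    class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf("ct_volume: %d x %d x %d voxels, %.4g mm isotropic (caudal -> cranial z)\n",
              d[1], d[2], d[3], x$voxel_size_mm))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(x$intensities), max(x$intensities)))
  invisible(x)
}

#' Integer label volume container
#'
#' Per-voxel ground-truth or output classes. The legend maps each integer
#' code present in `labels` to a class name; the phantom generator uses
#' `0 = outside`, `1 = lung`, `2 = intermediate`, `3 = soft`, `4 = bone`,
#' `5 = diaphragm`.
#'
#' @param labels integer 3D array of class codes.
#' @param legend named integer vector mapping class name -> code; must
#'   cover every code present in `labels`.
#' @param voxel_size_mm positive scalar voxel edge length in mm.
#' @return An object of class `label_volume`.
#' @export
label_volume <- function(labels, legend = tissue_legend(), voxel_size_mm = 0.1) {
  if (!is.array(labels) || length(dim(labels)) != 3L)
    stop("expected 3 dimensions, got ", length(dim(labels)))
  storage.mode(labels) <- "integer"
  present <- unique(as.vector(labels))
  missing <- setdiff(present, legend)
  if (length(missing))
    stop("legend does not cover label codes: ", paste(missing, collapse = ", "))
  if (voxel_size_mm <= 0) stop("voxel_size_mm must be positive")
  structure(
    list(labels = labels, legend = legend,
         voxel_size_mm = as.numeric(voxel_size_mm),
         axis = "caudocranial"),
    class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("label_volume: %d x %d x %d voxels, %.4g mm isotropic\n",
              d[1], d[2], d[3], x$voxel_size_mm))
  tab <- table(factor(as.vector(x$labels), levels = x$legend,
                      labels = names(x$legend)))
  print(tab)
  invisible(x)
}

#' Canonical tissue label legend
#'
#' @return Named integer vector mapping the six class names used throughout
#'   the package to their integer codes.
#' @export
tissue_legend <- function() {
  c(outside = 0L, lung = 1L, intermediate = 2L, soft = 3L,
    bone = 4L, diaphragm = 5L)
}

# shared helper: stop unless two grids have the same dimensions
check_same_grid <- function(a, b, what = "grids") {
  if (!identical(dim(a), dim(b)))
    stop(what, " have mismatched dimensions: ",
         paste(dim(a), collapse = "x"), " vs ", paste(dim(b), collapse = "x"))
  invisible(TRUE)
}
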