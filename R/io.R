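#' Read a CT or label volume from disk
#'
#' Supports NIfTI-1 (`.nii`, `.nii.gz`) and multipage TIFF (`.tif`,
#' `.tiff`). Voxel spacing is taken from the NIfTI header; TIFF volumes use
#' the JSON sidecar written by [write_volume()] when present, otherwise the
#' `voxel_size_mm` argument, otherwise 0.1 mm with a warning. If the NIfTI
#' affine indicates z decreasing cranially the volume is flipped to the
#' internal caudal-to-cranial convention (with a message), so every
#' downstream slice-index operation sees the same orientation.
#'
#' @param path file to read.
#' @param format `"auto"` (infer from extension), `"nifti"` or `"tiff"`.
#' @param voxel_size_mm optional spacing override for TIFF files lacking a
#'   sidecar.
#' @return A [ct_volume()] (or a [label_volume()] when the file was written
#'   from one and carries a label sidecar / integer NIfTI intent).
#' @export
read_volume <- function(path, format = c("auto", "nifti", "tiff"),
                        voxel_size_mm = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
    format <- switch(ext, nii = "nifti", tif = , tiff = "tiff",
                     stop("cannot infer format from extension '", ext,
                          "'; pass format="))
  }
  if (format == "nifti") read_volume_nifti(path) else
    read_volume_tiff(path, voxel_size_mm)
}

read_volume_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L) stop("expected 3 dimensions, got ", length(d))
  pd <- RNifti::pixdim(img)
  if (length(pd) < 3L || any(!is.finite(pd[1:3])) || any(pd[1:3] <= 0))
    stop("invalid voxel spacing in NIfTI header")
  if ((max(pd[1:3]) - min(pd[1:3])) / mean(pd[1:3]) > 0.01)
    stop("anisotropic voxel spacing beyond 1%: ",
         paste(signif(pd[1:3], 4), collapse = " x "))
  arr <- array(as.numeric(img), dim = d)
  xf <- tryCatch(RNifti::xform(img), error = function(e) NULL)
  if (!is.null(xf) && nrow(xf) >= 3 && xf[3, 3] < 0) {
    message("NIfTI z axis decreases cranially; flipping to caudal->cranial")
    arr <- arr[, , d[3]:1, drop = FALSE]
  }
  hdr <- RNifti::niftiHeader(img)
  if (!is.null(hdr$datatype) && hdr$datatype %in% c(2L, 4L, 8L, 512L) &&
      isTRUE(all(arr == round(arr))) && max(arr) <= 32L && min(arr) >= 0L) {
    # small non-negative integer codes: treat as labels
    return(label_volume(array(as.integer(arr), dim = d),
                        voxel_size_mm = mean(pd[1:3])))
  }
  ct_volume(arr, voxel_size_mm = mean(pd[1:3]))
}

read_volume_tiff <- function(path, voxel_size_mm = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) < 2L) stop("expected 3 dimensions, got 2 (single-page TIFF)")
  if (length(dim(pages[[1]])) != 2L)
    stop("expected grayscale pages; got multi-channel TIFF")
  # pages are y-by-x matrices; transpose to the internal x-by-y convention
  arr <- array(0, c(ncol(pages[[1]]), nrow(pages[[1]]), length(pages)))
  for (z in seq_along(pages)) arr[, , z] <- t(pages[[z]])
  side <- paste0(path, ".json")
  slope <- 1; intercept <- 0; kind <- "ct"; legend <- tissue_legend()
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    if (is.null(voxel_size_mm)) voxel_size_mm <- meta$voxel_size_mm
    if (!is.null(meta$slope)) slope <- meta$slope
    if (!is.null(meta$intercept)) intercept <- meta$intercept
    if (!is.null(meta$kind)) kind <- meta$kind
    if (!is.null(meta$legend))
      legend <- stats::setNames(as.integer(meta$legend), names(meta$legend))
  }
  if (is.null(voxel_size_mm)) {
    warning("no voxel spacing available for TIFF; assuming 0.1 mm")
    voxel_size_mm <- 0.1
  }
  arr <- arr * slope + intercept
  if (kind == "labels")
    label_volume(array(as.integer(round(arr)), dim = dim(arr)),
                 legend = legend, voxel_size_mm = voxel_size_mm)
  else
    ct_volume(arr, voxel_size_mm = voxel_size_mm)
}

#' Write a CT or label volume to disk
#'
#' NIfTI-1 output is lossless (float64 for intensities, int16 for labels).
#' TIFF output stores 32-bit floats rescaled to the unit interval; the
#' affine rescale, voxel spacing and (for labels) the legend go to a JSON
#' sidecar `<path>.json` so [read_volume()] can undo the transform. TIFF
#' intensity round trips are therefore exact only to float32 precision.
#'
#' @param v a [ct_volume()] or [label_volume()].
#' @param path destination; extension selects the format.
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path) {
  is_labels <- inherits(v, "label_volume")
  if (!is_labels && !inherits(v, "ct_volume"))
    stop("v must be a ct_volume or label_volume")
  arr <- if (is_labels) v$labels else v$intensities
  ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
  if (ext == "nii") {
    img <- RNifti::asNifti(arr)
    RNifti::pixdim(img) <- rep(v$voxel_size_mm, 3)
    RNifti::writeNifti(img, path,
                       datatype = if (is_labels) "int16" else "double")
  } else if (ext %in% c("tif", "tiff")) {
    rng <- range(arr)
    slope <- if (diff(rng) > 0) diff(rng) else 1
    scaled <- (arr - rng[1]) / slope
    pages <- lapply(seq_len(dim(arr)[3]), function(z) t(scaled[, , z]))
    tiff::writeTIFF(pages, path, bits.per.sample = 32L)
    meta <- list(voxel_size_mm = v$voxel_size_mm, slope = slope,
                 intercept = rng[1],
                 kind = if (is_labels) "labels" else "ct")
    if (is_labels) meta$legend <- as.list(v$legend)
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  } else stop("unsupported volume format: .", ext)
  invisible(path)
}

result_columns <- c("scan_id", "pct_lung", "pct_soft", "pct_intermediate",
                    "vol_lung_mm3", "vol_soft_mm3", "vol_intermediate_mm3",
                    "z_cranial", "z_interface", "n_slices")

#' Write / read a results table
#'
#' Fixed-schema CSV with one row per scan: tissue percentages of the
#' thoracic cavity, tissue volumes in cubic mm, axial bounds and slice
#' count. Percentages must sum to 100 per row.
#'
#' @param t data frame with the columns
#'   `scan_id, pct_lung, pct_soft, pct_intermediate, vol_lung_mm3,
#'   vol_soft_mm3, vol_intermediate_mm3, z_cranial, z_interface, n_slices`.
#' @param path CSV destination / source.
#' @return `write_results()` returns `path` invisibly; `read_results()`
#'   returns the validated data frame.
#' @export
write_results <- function(t, path) {
  t <- validate_results(t)
  write.csv(t[, result_columns], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  validate_results(read.csv(path, stringsAsFactors = FALSE))
}

validate_results <- function(t) {
  miss <- setdiff(result_columns, names(t))
  if (length(miss))
    stop("results table missing columns: ", paste(miss, collapse = ", "))
  s <- t$pct_lung + t$pct_soft + t$pct_intermediate
  bad <- which(abs(s - 100) > 1e-6)
  if (length(bad))
    stop("percentages do not sum to 100 in rows: ",
         paste(bad, collapse = ", "))
  t
}

#' Pipeline configuration
#'
#' Builds the validated configuration object consumed by [run_mlast()].
#' Defaults follow the published procedure: 3 density clusters with a
#' 100-iteration cap, 3-slice bone stacking, and a second mask pass using
#' the innermost 30% of rib points.
#'
#' @param bone_threshold `"auto"` (Otsu on the upper half of the intensity
#'   distribution) or a numeric threshold.
#' @param connectivity 3D connectivity for the largest-component step: 6,
#'   18 or 26.
#' @param stack_window odd integer, number of slices unioned when stacking
#'   the bone mask.
#' @param refine_fraction fraction of innermost rib points used in the
#'   second mask pass.
#' @param k_clusters number of density clusters (3 = lung / intermediate /
#'   soft; fixed at 3 in the published procedure).
#' @param max_iter Lloyd iteration cap.
#' @param restarts k-means restarts; best objective kept. Set 1 for a
#'   single seeded run as published.
#' @param min_region_px minimum 2D bone region area (pixels).
#' @param min_regions minimum rib regions for a slice to receive a mask.
#' @param min_airway_px minimum 2D airway component area for the
#'   tracheal-split test.
#' @param smoothing_window centered moving-average window (slices) for the
#'   diaphragm z-traces.
#' @param z_cranial optional manual override of the cranial cutoff slice.
#' @param seed integer seed controlling all pipeline randomness.
#' @return A named list of class `pipeline_config`.
#' @export
pipeline_config <- function(bone_threshold = "auto", connectivity = 26,
                            stack_window = 3, refine_fraction = 0.3,
                            k_clusters = 3, max_iter = 100, restarts = 3,
                            min_region_px = 3, min_regions = 3,
                            min_airway_px = 4, smoothing_window = 5,
                            z_cranial = NULL, seed = 1) {
  cfg <- list(bone_threshold = bone_threshold, connectivity = connectivity,
              stack_window = stack_window, refine_fraction = refine_fraction,
              k_clusters = k_clusters, max_iter = max_iter,
              restarts = restarts, min_region_px = min_region_px,
              min_regions = min_regions, min_airway_px = min_airway_px,
              smoothing_window = smoothing_window, z_cranial = z_cranial,
              seed = seed)
  problems <- character()
  chk <- function(ok, msg) if (!isTRUE(ok)) problems <<- c(problems, msg)
  if (!identical(cfg$bone_threshold, "auto"))
    chk(is.numeric(cfg$bone_threshold) && length(cfg$bone_threshold) == 1L &&
          is.finite(cfg$bone_threshold),
        "bone_threshold: must be \"auto\" or a finite scalar")
  chk(cfg$connectivity %in% c(6, 18, 26), "connectivity: must be 6, 18 or 26")
  chk(is.numeric(cfg$stack_window) && cfg$stack_window >= 1 &&
        cfg$stack_window %% 2 == 1, "stack_window: must be a positive odd integer")
  chk(is.numeric(cfg$refine_fraction) && cfg$refine_fraction > 0 &&
        cfg$refine_fraction <= 1, "refine_fraction: must be in (0, 1]")
  chk(is.numeric(cfg$k_clusters) && cfg$k_clusters >= 2,
      "k_clusters: must be an integer >= 2")
  chk(is.numeric(cfg$max_iter) && cfg$max_iter >= 1,
      "max_iter: must be a positive integer")
  chk(is.numeric(cfg$restarts) && cfg$restarts >= 1,
      "restarts: must be a positive integer")
  chk(is.numeric(cfg$min_region_px) && cfg$min_region_px >= 1,
      "min_region_px: must be >= 1")
  chk(is.numeric(cfg$min_regions) && cfg$min_regions >= 1,
      "min_regions: must be >= 1")
  chk(is.numeric(cfg$min_airway_px) && cfg$min_airway_px >= 1,
      "min_airway_px: must be >= 1")
  chk(is.numeric(cfg$smoothing_window) && cfg$smoothing_window >= 1 &&
        cfg$smoothing_window %% 2 == 1,
      "smoothing_window: must be a positive odd integer")
  if (!is.null(cfg$z_cranial))
    chk(is.numeric(cfg$z_cranial) && cfg$z_cranial >= 1,
        "z_cranial: must be a slice index >= 1")
  chk(is.numeric(cfg$seed) && length(cfg$seed) == 1L && is.finite(cfg$seed),
      "seed: must be a finite integer")
  if (length(problems))
    stop("invalid pipeline configuration:\n  ",
         paste(problems, collapse = "\n  "))
  # normalize numeric storage so configs read from files compare equal
  num_fields <- c("connectivity", "stack_window", "refine_fraction",
                  "k_clusters", "max_iter", "restarts", "min_region_px",
                  "min_regions", "min_airway_px", "smoothing_window", "seed")
  cfg[num_fields] <- lapply(cfg[num_fields], as.numeric)
  if (!identical(cfg$bone_threshold, "auto"))
    cfg$bone_threshold <- as.numeric(cfg$bone_threshold)
  if (!is.null(cfg$z_cranial)) cfg$z_cranial <- as.integer(cfg$z_cranial)
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration file
#'
#' Flat YAML or JSON key-value document validated against the built-in
#' defaults of [pipeline_config()]; unknown keys are rejected, missing keys
#' fall back to the defaults.
#'
#' @param path YAML (`.yaml`/`.yml`) or JSON (`.json`) file.
#' @return A `pipeline_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  vals <- switch(ext,
                 yaml = , yml = yaml::read_yaml(path),
                 json = jsonlite::read_json(path, simplifyVector = TRUE),
                 stop("unsupported config format: .", ext))
  if (is.null(vals)) vals <- list()
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  do.call(pipeline_config, vals)
}
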