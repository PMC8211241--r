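# Full pipeline orchestration: mask -> cluster -> classify -> bounds ->
# diaphragm removal -> tissue percentages and volumes.

`%||%` <- function(a, b) if (is.null(a)) b else a

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("[", name, "] ", conditionMessage(e), call. = FALSE))
}

#' Run the full automated segmentation pipeline
#'
#' Executes bone thresholding, largest-component selection, slice
#' stacking, the two-pass thoracic mask, scan-wide 1-D k-means density
#' clustering, tissue classification, the tracheal-bifurcation cranial
#' cutoff, the heart-diaphragm interface, diaphragm segmentation and
#' removal, and reports per-class voxel counts, volumes (mm^3) and
#' percentages of the bounded, diaphragm-free thoracic cavity.
#' Deterministic given the configuration seed.
#'
#' One density model is fitted per scan on the pooled in-mask intensities
#' (intra-scan normalization); above 5e6 in-mask voxels a deterministic
#' stride subsample fits the model and all voxels are then classified,
#' which bounds memory without changing assignments.
#'
#' @param v a [ct_volume()].
#' @param cfg a [pipeline_config()].
#' @param scan_id identifier recorded in the result (default "scan").
#' @param keep_volumes keep the mask / segmentation / diaphragm arrays in
#'   the result (default TRUE; set FALSE for large batches).
#' @return A `segmentation_result`: per-class `counts`, `volumes_mm3`,
#'   `pct` (lung / intermediate / soft, summing to 100),
#'   `combined_burden_pct` (soft + intermediate), `bounds`, the cluster
#'   `model`, and a per-stage `log`.
#' @export
run_mlast <- function(v, cfg = pipeline_config(), scan_id = "scan",
                      keep_volumes = TRUE) {
  stopifnot(inherits(v, "ct_volume"))
  if (!inherits(cfg, "pipeline_config")) cfg <- do.call(pipeline_config, cfg)
  log <- character()
  note <- function(...) log <<- c(log, sprintf(...))

  mask <- run_stage("cavity_mask", build_thoracic_mask(v, cfg))
  note("cavity_mask: %d in-mask voxels, bone threshold %.4g, %d slices masked",
       sum(mask$mask), mask$bone$threshold, sum(apply(mask$mask, 3, any)))

  vals <- v$intensities[mask$mask]
  fit_vals <- if (length(vals) > 5e6) {
    stride <- ceiling(length(vals) / 5e6)
    vals[seq(1L, length(vals), by = stride)]
  } else vals
  model <- run_stage("density_cluster",
                     kmeans_1d(fit_vals, k = cfg$k_clusters,
                               max_iter = cfg$max_iter,
                               restarts = cfg$restarts, seed = cfg$seed))
  note("density_cluster: centroids %s, %d iterations, converged %s, objective %.6g",
       paste(signif(model$centroids, 4), collapse = "/"),
       model$n_iterations, model$converged, model$objective)

  seg <- run_stage("classify", classify_tissue(v, mask, model))
  z_cranial <- if (!is.null(cfg$z_cranial)) as.integer(cfg$z_cranial) else
    run_stage("cranial_cutoff", cranial_cutoff(seg, mask, cfg$min_airway_px))
  z_interface <- run_stage("interface", heart_diaphragm_interface(seg, mask))
  if (z_interface >= z_cranial)
    stop("[bounds] heart-diaphragm interface (", z_interface,
         ") not caudal of the cranial cutoff (", z_cranial, ")")
  bounds <- axial_bounds(z_cranial, z_interface)
  note("bounds: z_cranial %d, z_interface %d", z_cranial, z_interface)

  dia <- run_stage("diaphragm",
                   segment_diaphragm(v, mask, z_interface,
                                     cfg$smoothing_window))
  note("diaphragm: %d voxels removed", sum(dia$mask))
  seg_b <- run_stage("bounds", apply_bounds(seg, bounds, dia))

  counts <- c(lung = sum(seg_b$classes == 1L),
              intermediate = sum(seg_b$classes == 2L),
              soft = sum(seg_b$classes == 3L))
  tot <- sum(counts)
  if (tot == 0) stop("[fractions] no tissue voxels remain within bounds")
  pct <- 100 * counts / tot
  vox_mm3 <- v$voxel_size_mm^3
  note("fractions: lung %.2f%%, intermediate %.2f%%, soft %.2f%%",
       pct[["lung"]], pct[["intermediate"]], pct[["soft"]])

  structure(list(
    scan_id = scan_id,
    counts = counts,
    volumes_mm3 = counts * vox_mm3,
    pct = pct,
    combined_burden_pct = pct[["soft"]] + pct[["intermediate"]],
    bounds = bounds,
    model = model,
    voxel_size_mm = v$voxel_size_mm,
    mask = if (keep_volumes) mask else NULL,
    segmentation = if (keep_volumes) seg_b else NULL,
    diaphragm = if (keep_volumes) dia else NULL,
    log = log), class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat("segmentation_result:", x$scan_id, "\n")
  cat(sprintf("  lung %.2f%%  intermediate %.2f%%  soft %.2f%%  (combined burden %.2f%%)\n",
              x$pct[["lung"]], x$pct[["intermediate"]], x$pct[["soft"]],
              x$combined_burden_pct))
  cat(sprintf("  volumes (mm^3): lung %.2f, intermediate %.2f, soft %.2f\n",
              x$volumes_mm3[["lung"]], x$volumes_mm3[["intermediate"]],
              x$volumes_mm3[["soft"]]))
  cat(sprintf("  bounds: z %d..%d (interface %d), %d slices\n",
              x$bounds$z_caudal, x$bounds$z_cranial, x$bounds$z_interface,
              x$bounds$n_slices_used))
  invisible(x)
}

#' Convert segmentation results to the fixed-schema results table
#'
#' @param results a `segmentation_result` or list of them.
#' @return Data frame with the [write_results()] column schema.
#' @export
results_table <- function(results) {
  if (inherits(results, "segmentation_result")) results <- list(results)
  do.call(rbind, lapply(results, function(r) {
    data.frame(scan_id = r$scan_id,
               pct_lung = r$pct[["lung"]],
               pct_soft = r$pct[["soft"]],
               pct_intermediate = r$pct[["intermediate"]],
               vol_lung_mm3 = r$volumes_mm3[["lung"]],
               vol_soft_mm3 = r$volumes_mm3[["soft"]],
               vol_intermediate_mm3 = r$volumes_mm3[["intermediate"]],
               z_cranial = r$bounds$z_cranial,
               z_interface = r$bounds$z_interface,
               n_slices = r$bounds$n_slices_used,
               stringsAsFactors = FALSE)
  }))
}
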