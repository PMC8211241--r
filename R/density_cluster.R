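# One-dimensional k-means density clustering of in-cavity voxels.
#
# The whole-scan pooled intensities inside the thoracic mask are split
# into k = 3 density clusters (Lloyd iterations with k++ seeding, at most
# 100 iterations); the cluster with the lowest-density centroid is lung,
# the highest soft tissue, the middle one intermediate. Clustering the
# scan's own density spectrum, rather than applying fixed thresholds,
# makes the segmentation robust to calibration drift between scans.

#' k-means++ seeding for 1-D values
#'
#' The first centroid is drawn uniformly from the values; each subsequent
#' centroid is drawn with probability proportional to the squared distance
#' to its nearest already-chosen centroid. Uses R's global RNG stream.
#'
#' @param values numeric vector with at least `k` distinct values.
#' @param k number of centroids.
#' @return Numeric vector of `k` distinct seed centroids.
#' @export
kmeans_pp_seed <- function(values, k) {
  if (length(unique(values)) < k)
    stop("degenerate intensity distribution: fewer than k distinct values")
  n <- length(values)
  centers <- numeric(k)
  centers[1] <- values[sample.int(n, 1L)]
  d2 <- (values - centers[1])^2
  for (j in seq_len(k - 1L) + 1L) {
    if (all(d2 == 0)) stop("degenerate intensity distribution during seeding")
    centers[j] <- values[sample.int(n, 1L, prob = d2)]
    d2 <- pmin(d2, (values - centers[j])^2)
  }
  centers
}

# nearest-centroid assignment for sorted centroids; exact midpoints go to
# the lower-density cluster (documented tie rule)
assign_1d <- function(values, centers_sorted) {
  mids <- (centers_sorted[-length(centers_sorted)] + centers_sorted[-1]) / 2
  findInterval(values, mids, left.open = TRUE) + 1L
}

#' One-dimensional k-means (Lloyd) with k++ seeding
#'
#' Alternates nearest-centroid assignment and centroid-mean updates until
#' assignments stop changing or `max_iter` is reached. A cluster emptied
#' during iteration is re-seeded at the value farthest from its nearest
#' centroid (documented repair). With `restarts > 1` the best objective
#' over independent seedings is kept; the first restart then seeds
#' deterministically at the `(2j - 1) / 2k` quantiles (a strong 1-D
#' initializer), the remainder use k++. `restarts = 1` is a single pure
#' k++ run.
#'
#' @param values numeric vector to cluster.
#' @param k number of clusters (default 3).
#' @param max_iter iteration cap (default 100).
#' @param restarts independent k++ seedings (default 1).
#' @param seed optional integer; when given, the run is wrapped in a local
#'   RNG seed so results are reproducible without touching global state.
#' @return A `tissue_cluster_model`: list with ascending `centroids`,
#'   `class_map` (lowest -> lung, middle -> intermediate, highest -> soft,
#'   for k = 3), `n_iterations`, `converged`, and `objective`
#'   (within-cluster sum of squared deviations).
#' @export
kmeans_1d <- function(values, k = 3, max_iter = 100, restarts = 1,
                      seed = NULL) {
  run_all <- function() {
    best <- NULL
    for (r in seq_len(restarts)) {
      seeds <- NULL
      if (r == 1L && restarts > 1L) {
        q <- unname(quantile(values, (2 * seq_len(k) - 1) / (2 * k)))
        if (length(unique(q)) == k) seeds <- q
      }
      fit <- kmeans_1d_once(values, k, max_iter, seeds)
      if (is.null(best) || fit$objective < best$objective) best <- fit
    }
    best
  }
  fit <- if (is.null(seed)) run_all() else with_local_seed(seed, run_all())
  cls <- if (k == 3) c("lung", "intermediate", "soft") else
    paste0("cluster", seq_len(k))
  fit$class_map <- stats::setNames(seq_len(k), cls)
  class(fit) <- "tissue_cluster_model"
  fit
}

kmeans_1d_once <- function(values, k, max_iter, seeds = NULL) {
  centers <- sort(if (is.null(seeds)) kmeans_pp_seed(values, k) else seeds)
  assign_prev <- NULL
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    a <- assign_1d(values, centers)
    if (!is.null(assign_prev) && identical(a, assign_prev)) {
      converged <- TRUE
      iter <- iter - 1L
      break
    }
    assign_prev <- a
    sums <- vapply(seq_len(k), function(j) sum(values[a == j]), numeric(1))
    cnts <- tabulate(a, nbins = k)
    empty <- which(cnts == 0L)
    for (j in empty) {
      # re-seed an emptied cluster at the point farthest from its nearest
      # centroid, then re-assign
      d2 <- vapply(values, function(x) min((x - centers)^2), numeric(1))
      centers[j] <- values[which.max(d2)]
      a <- assign_1d(values, sort(centers))
      sums <- vapply(seq_len(k), function(jj) sum(values[a == jj]), numeric(1))
      cnts <- tabulate(a, nbins = k)
    }
    centers <- sort(sums / cnts)
  }
  a <- assign_1d(values, centers)
  list(centroids = centers,
       n_iterations = iter,
       converged = converged,
       objective = sum((values - centers[a])^2))
}

#' Classify in-mask voxels by nearest density centroid
#'
#' Every voxel inside the thoracic mask is assigned the tissue class of
#' the nearest cluster centroid (exact midpoints go to the lower-density
#' class); voxels outside the mask get class `outside`.
#'
#' @param v a [ct_volume()].
#' @param mask a `thoracic_mask` from [build_thoracic_mask()], or a
#'   logical array of the same dimensions.
#' @param model a `tissue_cluster_model` from [kmeans_1d()] fitted on this
#'   volume's in-mask intensities.
#' @return A `tissue_segmentation`: list with integer array `classes`
#'   (0 outside, 1 lung, 2 intermediate, 3 soft), the `model` and the mask
#'   provenance.
#' @export
classify_tissue <- function(v, mask, model) {
  stopifnot(inherits(v, "ct_volume"), inherits(model, "tissue_cluster_model"))
  m <- if (inherits(mask, "thoracic_mask")) mask$mask else mask
  check_same_grid(v$intensities, m, "volume and mask")
  if (!any(m)) stop("thoracic mask is empty")
  cls <- array(0L, dim(m))
  cls[m] <- assign_1d(v$intensities[m], model$centroids)
  structure(list(classes = cls, model = model,
                 legend = c(outside = 0L, lung = 1L, intermediate = 2L,
                            soft = 3L)),
            class = "tissue_segmentation")
}
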