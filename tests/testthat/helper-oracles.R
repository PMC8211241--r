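# Independent oracles, kept deliberately naive and separate from the
# implementation paths they check.

# exact 1-D k-means optimum by dynamic programming over contiguous
# partitions of the sorted values (the 1-D optimum is contiguous)
kmeans_1d_optimum <- function(values, k) {
  x <- sort(values)
  n <- length(x)
  cs <- cumsum(x)
  cs2 <- cumsum(x^2)
  sse <- function(i, j) { # within-SSE of x[i..j]
    s <- cs[j] - if (i > 1) cs[i - 1] else 0
    s2 <- cs2[j] - if (i > 1) cs2[i - 1] else 0
    s2 - s^2 / (j - i + 1)
  }
  dp <- matrix(Inf, k, n)
  for (j in seq_len(n)) dp[1, j] <- sse(1, j)
  if (k > 1) {
    for (m in 2:k) {
      for (j in m:n) {
        best <- Inf
        for (i in m:j) {
          cand <- dp[m - 1, i - 1] + sse(i, j)
          if (cand < best) best <- cand
        }
        dp[m, j] <- best
      }
    }
  }
  dp[k, n]
}

# brute-force flood fill (4/8-connected 2D, 6/26-connected 3D), queue-based
flood_components <- function(mask, connectivity) {
  d <- dim(mask)
  is3d <- length(d) == 3
  offs <- list()
  for (dz in if (is3d) -1:1 else 0) for (dy in -1:1) for (dx in -1:1) {
    s <- abs(dx) + abs(dy) + abs(dz)
    if (s == 0) next
    keep <- switch(as.character(connectivity),
                   "4" = s == 1, "6" = s == 1, "8" = TRUE, "26" = TRUE, FALSE)
    if (keep) offs[[length(offs) + 1]] <- c(dx, dy, dz)
  }
  lab <- array(0L, d)
  nxt <- 0L
  coords <- which(mask, arr.ind = TRUE)
  if (!is3d && !is.matrix(coords)) coords <- matrix(coords, ncol = 2)
  for (r in seq_len(nrow(coords))) {
    p0 <- coords[r, ]
    if (lab[matrix(p0, 1)] != 0L) next
    nxt <- nxt + 1L
    queue <- list(p0)
    lab[matrix(p0, 1)] <- nxt
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (o in offs) {
        q <- p + o[seq_along(p)]
        if (any(q < 1) || any(q > d)) next
        qm <- matrix(q, 1)
        if (mask[qm] && lab[qm] == 0L) {
          lab[qm] <- nxt
          queue[[length(queue) + 1]] <- q
        }
      }
    }
  }
  lab
}

# separable Chebyshev (box) erosion of a 3D logical array by k voxels
erode_box <- function(mask, k) {
  shift_and <- function(m, axis) {
    d <- dim(m)
    idx <- function(off) {
      i <- pmin(pmax(seq_len(d[axis]) + off, 1L), d[axis])
      switch(axis, m[i, , , drop = FALSE], m[, i, , drop = FALSE],
             m[, , i, drop = FALSE])
    }
    # clamped shifts keep border voxels eroded only by in-grid neighbours
    m & idx(-1L) & idx(1L)
  }
  for (i in seq_len(k)) for (ax in 1:3) mask <- shift_and(mask, ax)
  mask
}

# independent clockwise angular sort used to cross-check clockwise_order
angle_sort_oracle <- function(points, center) {
  ang <- atan2(points[, 2] - center[2], points[, 1] - center[1])
  key <- (pi - ang) %% (2 * pi)
  r <- sqrt((points[, 1] - center[1])^2 + (points[, 2] - center[2])^2)
  points[order(key, r), , drop = FALSE]
}
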