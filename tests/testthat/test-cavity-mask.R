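test_that("bone thresholding isolates high-density voxels", {
  v <- ct_volume(array(0, c(8, 8, 8)) + 0.0)
  expect_error(threshold_bone(v, 0.5), "no bone voxels")
  x <- array(0, c(8, 8, 8)); x[3, 4, 5] <- 0.9
  bm <- threshold_bone(ct_volume(x), 0.8)
  expect_equal(sum(bm$mask), 1)
  expect_true(bm$mask[3, 4, 5])
  # auto threshold on a phantom recovers the true bone compartment
  ph <- small_phantom()
  bm2 <- threshold_bone(ph$volume, "auto")
  expect_gt(dice(bm2$mask, true_class_mask(ph$labels, "bone")), 0.95)
})

test_that("largest 3D component selection matches a flood-fill oracle", {
  m <- array(FALSE, c(12, 12, 6))
  m[2:4, 2:4, 2] <- TRUE            # 9 voxels
  m[9:10, 9, 3] <- TRUE             # 2 voxels
  bm <- structure(list(mask = m, threshold = 1, connectivity = NA),
                  class = "bone_mask")
  out <- largest_component_3d(bm, 26)
  expect_equal(sum(out$mask), 9)
  expect_true(all(out$mask[2:4, 2:4, 2]))
  # oracle comparison on random masks, both connectivities
  set.seed(21)
  for (conn in c(6, 26)) {
    m2 <- array(runif(10 * 10 * 5) < 0.2, c(10, 10, 5))
    m2[1, 1, 1] <- TRUE
    lab <- flood_components(m2, conn)
    sizes <- tabulate(lab[lab > 0])
    got <- largest_component_3d(structure(list(mask = m2),
                                          class = "bone_mask"), conn)
    expect_equal(sum(got$mask), max(sizes))
  }
  # equal-size tie goes to the component with the smallest linear index
  t2 <- array(FALSE, c(10, 4, 4))
  t2[1:5, 1, 1] <- TRUE
  t2[1:5, 3, 3] <- TRUE
  tied <- largest_component_3d(structure(list(mask = t2),
                                         class = "bone_mask"), 6)
  expect_true(all(tied$mask[1:5, 1, 1]))
  expect_false(any(tied$mask[, 3, 3]))
})

test_that("slice stacking unions a centred window with clamped ends", {
  m <- array(FALSE, c(6, 6, 20))
  m[3, 3, 10] <- TRUE
  bm <- structure(list(mask = m), class = "bone_mask")
  st <- stack_slices(bm, 3)
  expect_equal(which(apply(st$mask, 3, any)), 9:11)
  expect_identical(stack_slices(bm, 1)$mask, m)
  expect_error(stack_slices(bm, 2), "odd")
  # a full-z column is unchanged
  m2 <- array(FALSE, c(6, 6, 20)); m2[2, 2, ] <- TRUE
  bm2 <- structure(list(mask = m2), class = "bone_mask")
  expect_identical(stack_slices(bm2, 3)$mask, m2)
})

test_that("rib regions are 8-connected components with centroids", {
  sl <- matrix(FALSE, 20, 20)
  sl[2:4, 2:4] <- TRUE
  sl[10:12, 15:17] <- TRUE
  regs <- rib_regions(sl)
  expect_length(regs, 2)
  cents <- t(vapply(regs, `[[`, numeric(2), "centroid"))
  expect_equal(cents[order(cents[, 1]), ], rbind(c(3, 3), c(11, 16)))
  expect_length(rib_regions(matrix(FALSE, 5, 5)), 0)
  # area filter
  sl2 <- matrix(FALSE, 10, 10); sl2[1, 1] <- TRUE; sl2[5:8, 5] <- TRUE
  expect_length(rib_regions(sl2, min_region_px = 3), 1)
})

test_that("a phantom slice shows 2 * rib_count + 1 bone regions", {
  ph <- small_phantom()
  spec <- small_spec()
  bone <- largest_component_3d(threshold_bone(ph$volume, "auto"), 26)
  # pick a mid-thorax slice without an intercostal bridge
  zlo <- spec$geometry$z_rib_lo
  z <- zlo + 31  # (z - z_rib_lo) %% 3 != 0
  regs <- rib_regions(bone$mask[, , z])
  expect_equal(length(regs), 2 * spec$rib_count + 1)
})

test_that("innermost point selection is a distance sort", {
  # two concentric square rings; fraction 0.5 returns exactly the inner one
  ring <- function(r) {
    th <- seq(0, 2 * pi, length.out = 4 * r)[-1]
    unique(round(cbind(50 + r * cos(th), 50 + r * sin(th))))
  }
  inner <- ring(10); outer <- ring(20)
  n <- min(nrow(inner), nrow(outer))
  regions <- list(list(boundary = inner[1:n, ]), list(boundary = outer[1:n, ]))
  got <- innermost_points(regions, c(50, 50), 0.5)
  d <- sqrt((got[, 1] - 50)^2 + (got[, 2] - 50)^2)
  expect_true(all(d < 15))
  expect_equal(nrow(got), n)
  # fraction 1 returns the whole pool
  expect_equal(nrow(innermost_points(regions, c(50, 50), 1)), 2 * n)
  expect_error(innermost_points(list(), c(0, 0)), "no rib regions")
})

test_that("clockwise ordering matches an independent angular sort", {
  ctr <- c(0, 0)
  nesw <- rbind(N = c(0, 1), E = c(1, 0), S = c(0, -1), W = c(-1, 0))
  ord <- clockwise_order(nesw, ctr)
  # start at angle pi (W), then decreasing angle: W, N, E, S; as a cyclic
  # order this is N, E, S, W
  expect_equal(rownames(ord), c("W", "N", "E", "S"))
  set.seed(33)
  pts <- cbind(rnorm(100), rnorm(100))
  got <- clockwise_order(pts, ctr)
  expect_equal(got, angle_sort_oracle(pts, ctr))
  ang <- (pi - atan2(got[, 2], got[, 1])) %% (2 * pi)
  expect_true(all(diff(ang) >= 0))
  expect_error(clockwise_order(matrix(0, 5, 2), ctr), "coincide")
})

test_that("spline outlines enclose the expected area", {
  th <- seq(0, 2 * pi, length.out = 17)[-17]
  circ <- cbind(50 + 30 * cos(th), 50 + 30 * sin(th))
  m <- spline_outline(clockwise_order(circ, c(50, 50)), c(100, 100))
  expect_lt(abs(sum(m) - pi * 30^2) / (pi * 30^2), 0.02)
  # dense points along a square boundary: fill stays within 1 px of it
  sq <- 20:60
  pts <- rbind(cbind(sq, 20), cbind(60, sq), cbind(rev(sq), 60),
               cbind(20, rev(sq)))
  ms <- spline_outline(clockwise_order(pts, c(40, 40)), c(80, 80))
  expect_true(all(ms[22:58, 22:58]))
  expect_false(any(ms[-(19:61), ]) || any(ms[, -(19:61)]))
  expect_error(spline_outline(circ[1:3, ], c(100, 100)), "at least 4")
})

test_that("thoracic mask matches the phantom cavity and excludes bone", {
  ph <- small_phantom()
  res <- small_result()
  mask <- res$mask
  expect_false(any(mask$mask & mask$bone$mask))
  cav <- true_cavity(ph$labels)
  zmid <- mid_thorax_slices(ph$labels)
  expect_gt(dice(mask$mask[, , zmid], cav[, , zmid]), 0.90)
  # refinement never grows the cavity
  ok <- !is.na(mask$pass1_area) & !is.na(mask$pass2_area)
  expect_true(all(mask$pass2_area[ok] <= mask$pass1_area[ok]))
  # per-slice area varies smoothly
  areas <- apply(mask$mask, 3, sum)
  nz <- which(areas > 0)
  rel <- abs(diff(areas[nz])) / pmax(areas[nz][-length(nz)], 1)
  expect_lt(max(rel), 0.30)
})

test_that("mask refinement stays shrink-only under motion blur", {
  spec <- small_spec(motion_blur_sd = 0.8)
  ph <- generate_phantom(spec, seed = 6)
  mask <- build_thoracic_mask(ph$volume, pipeline_config())
  ok <- !is.na(mask$pass1_area) & !is.na(mask$pass2_area)
  expect_gt(sum(ok), 10)
  expect_true(all(mask$pass2_area[ok] <= mask$pass1_area[ok]))
  zmid <- mid_thorax_slices(ph$labels)
  expect_gt(dice(mask$mask[, , zmid], true_cavity(ph$labels)[, , zmid]), 0.85)
})

test_that("volumes without a ribcage are rejected", {
  v <- ct_volume(array(rnorm(16 * 16 * 8, 0.1, 0.02), c(16, 16, 8)))
  expect_error(build_thoracic_mask(v, pipeline_config(bone_threshold = 5)),
               "no bone voxels")
})
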