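# build a minimal synthetic segmentation + mask pair for bound tests
synthetic_seg <- function(classes) {
  structure(list(classes = classes,
                 legend = c(outside = 0L, lung = 1L, intermediate = 2L,
                            soft = 3L)),
            class = "tissue_segmentation")
}

test_that("cranial cutoff finds the slice where the airway splits", {
  nz <- 40
  cls <- array(3L, c(40, 40, nz))
  bif <- 36
  for (z in seq_len(nz)) {
    if (z > bif) cls[19:22, 19:22, z] <- 1L
    else { cls[15:17, 19:21, z] <- 1L; cls[24:26, 19:21, z] <- 1L }
  }
  m <- array(TRUE, c(40, 40, nz))
  expect_equal(cranial_cutoff(synthetic_seg(cls), m), bif)
  # a single airway column everywhere -> no split detectable
  cls1 <- array(3L, c(40, 40, nz))
  cls1[19:22, 19:22, ] <- 1L
  expect_error(cranial_cutoff(synthetic_seg(cls1), m), "not detected")
})

test_that("phantom bifurcation is recovered and noise-stable", {
  spec <- small_spec()
  res <- small_result()
  expect_lte(abs(res$bounds$z_cranial - spec$trachea_bifurcation_z), 1)
  # a different noise seed gives the identical cutoff
  ph2 <- generate_phantom(spec, seed = 77)
  res2 <- run_mlast(ph2$volume, pipeline_config(seed = 4))
  expect_equal(res2$bounds$z_cranial, res$bounds$z_cranial)
})

test_that("heart-diaphragm interface is the argmax lung slice, caudal ties", {
  cls <- array(0L, c(10, 10, 50))
  m <- array(FALSE, c(10, 10, 50))
  m[2:9, 2:9, ] <- TRUE
  cls[2:9, 2:9, ] <- 3L
  # lung fractions peaking at z = 30
  nlung <- round(64 * c(rep(0.2, 29), 0.9, rep(0.4, 20)))
  for (z in 1:50) cls[2:(1 + nlung[z] %/% 8), 2:9, z] <- 1L
  expect_equal(heart_diaphragm_interface(synthetic_seg(cls), m), 30)
  # equal maxima at 20 and 40: caudal wins
  cls2 <- array(3L, c(10, 10, 50)); cls2[, , ] <- 3L
  cls2[2:5, 2:9, 20] <- 1L
  cls2[2:5, 2:9, 40] <- 1L
  expect_equal(heart_diaphragm_interface(synthetic_seg(cls2), m), 20)
  expect_error(heart_diaphragm_interface(synthetic_seg(cls),
                                         array(FALSE, c(10, 10, 50))),
               "empty")
})

test_that("phantom interface sits at the diaphragm dome apex", {
  spec <- small_spec()
  res <- small_result()
  expect_lte(abs(res$bounds$z_interface - spec$diaphragm_apex_z), 2)
})

test_that("column inflection matches the logistic closed form", {
  # logistic step from soft (0.55) down to lung (0.05) centred at z0:
  # the second derivative vanishes at the centre, the gradient is
  # steepest there
  nx <- 7; ny <- 7; nzz <- 40; z0 <- 10
  x <- array(0, c(nx, ny, nzz))
  for (z in 1:nzz) x[, , z] <- 0.05 + 0.5 / (1 + exp((z - z0) / 1.5))
  m <- array(TRUE, c(nx, ny, nzz))
  dm <- segment_diaphragm(ct_volume(x), m, z_interface = 35)
  zs <- apply(dm$mask[4, 4, , drop = FALSE], 3, any)
  top <- max(which(zs))
  expect_lte(abs(top - z0), 1)
  # a flat trace contributes no diaphragm anywhere
  flat <- ct_volume(array(0.55, c(nx, ny, nzz)))
  dm2 <- segment_diaphragm(flat, m, z_interface = 35)
  expect_equal(sum(dm2$mask), 0)
  # z_interface at the caudal end -> empty mask with warning
  expect_warning(dm3 <- segment_diaphragm(flat, m, 1), "caudal")
  expect_equal(sum(dm3$mask), 0)
})

test_that("phantom diaphragm is recovered with high overlap", {
  ph <- small_phantom()
  res <- small_result()
  expect_gt(dice(res$diaphragm$mask, true_class_mask(ph$labels, "diaphragm")),
            0.7)
  # diaphragm mask is a subset of the thoracic mask, empty above interface
  expect_true(all(res$mask$mask[res$diaphragm$mask]))
  nz <- dim(res$diaphragm$mask)[3]
  if (res$bounds$z_interface < nz)
    expect_false(any(res$diaphragm$mask[, , (res$bounds$z_interface + 1):nz]))
})

test_that("apply_bounds trims cranially and removes the diaphragm exactly", {
  cls <- array(1L, c(6, 6, 30))
  seg <- synthetic_seg(cls)
  b <- axial_bounds(z_cranial = 29, z_interface = 10)
  # empty diaphragm, (almost) full z range: identity below the cutoff
  dempty <- structure(list(mask = array(FALSE, c(6, 6, 30)), z_interface = 10),
                      class = "diaphragm_mask")
  out <- apply_bounds(seg, b, dempty)
  expect_true(all(out$classes[, , 1:29] == 1L))
  expect_true(all(out$classes[, , 30] == 0L))
  # all-diaphragm: every voxel removed
  dall <- structure(list(mask = array(TRUE, c(6, 6, 30)), z_interface = 10),
                    class = "diaphragm_mask")
  out2 <- apply_bounds(seg, b, dall)
  expect_equal(sum(out2$classes), 0)
  expect_error(axial_bounds(5, 9), "z_caudal <= z_interface")
})

test_that("counts conserve the bounded mask census exactly", {
  res <- small_result()
  m <- res$mask$mask
  b <- res$bounds
  census <- sum(m[, , seq_len(b$z_cranial)]) -
    sum(res$diaphragm$mask[, , seq_len(b$z_cranial)])
  expect_identical(sum(res$counts), as.integer(census))
})

test_that("diaphragm removal does not raise soft percentage on tumor-free phantoms", {
  res <- small_result()
  # recompute soft share without diaphragm removal: re-run bounds on the
  # un-trimmed segmentation
  ph <- small_phantom()
  model <- res$model
  seg_raw <- classify_tissue(ph$volume, res$mask, model)
  seg_b <- apply_bounds(seg_raw, res$bounds, NULL)
  soft_with_dia <- mean(seg_b$classes[seg_b$classes > 0] == 3L)
  soft_removed <- mean(res$segmentation$classes[res$segmentation$classes > 0] == 3L)
  expect_lte(soft_removed, soft_with_dia + 1e-12)
})
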