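test_that("k++ seeding excludes zero-distance picks and spreads centroids", {
  set.seed(1)
  for (i in 1:20) {
    s <- sort(kmeans_pp_seed(c(0, 0, 0, 100, 100), 2))
    expect_equal(s, c(0, 100))
  }
  expect_error(kmeans_pp_seed(rep(3, 10), 3), "degenerate")
})

test_that("k++ seeding follows the squared-distance law", {
  # hand enumeration for values {0, 1, 10}, k = 2:
  #   first 0  -> P(second = 10) = 100 / 101
  #   first 1  -> P(second = 10) =  81 / 82
  #   first 10 -> P(second = 0)  = 100 / 181
  # so P({0,10}) = (100/101 + 81/82 + 100/181) / 3, P({1,10}), P({0,1})
  p_0_10 <- (100 / 101 + 100 / 181) / 3
  p_1_10 <- (81 / 82 + 81 / 181) / 3
  p_0_1 <- (1 / 101 + 1 / 82) / 3
  expect_equal(p_0_10 + p_1_10 + p_0_1, 1, tolerance = 1e-12)
  n <- 4000
  picks <- withr::with_seed(99, replicate(n, paste(
    sort(kmeans_pp_seed(c(0, 1, 10), 2)), collapse = ",")))
  for (pair in list(c("0,10", p_0_10), c("1,10", p_1_10), c("0,1", p_0_1))) {
    p <- as.numeric(pair[2])
    emp <- mean(picks == pair[1])
    expect_lt(abs(emp - p), 3 * sqrt(p * (1 - p) / n))
  }
})

test_that("1-D k-means recovers exact small optima", {
  fit <- kmeans_1d(c(1, 1, 1, 5, 5, 9, 9), k = 3, seed = 2)
  expect_equal(fit$centroids, c(1, 5, 9))
  expect_equal(fit$objective, 0)
  expect_true(fit$converged)
  fit2 <- kmeans_1d(c(0, 1, 10, 11), k = 2, seed = 2)
  expect_equal(fit2$centroids, c(0.5, 10.5))
  expect_named(fit$class_map, c("lung", "intermediate", "soft"))
  expect_true(all(diff(fit$centroids) > 0))
})

test_that("objective is self-consistent and near the exact optimum", {
  set.seed(7)
  worst <- 0
  for (i in 1:50) {
    n <- sample(20:200, 1)
    x <- c(rnorm(n %/% 3, 0, 0.5), rnorm(n %/% 3, 3, 0.7),
           rnorm(n - 2 * (n %/% 3), 8, 1))
    fit <- kmeans_1d(x, k = 3, restarts = 5, seed = i)
    # objective equals the assignment-recomputed value
    mids <- (fit$centroids[-3] + fit$centroids[-1]) / 2
    a <- findInterval(x, mids, left.open = TRUE) + 1L
    expect_equal(fit$objective, sum((x - fit$centroids[a])^2),
                 tolerance = 1e-10)
    opt <- kmeans_1d_optimum(x, 3)
    expect_lte(fit$objective, opt * 1.05 + 1e-9)
    worst <- max(worst, fit$objective / max(opt, 1e-12))
  }
  expect_lt(worst, 1.05)
})

test_that("clustering is equivariant under positive affine transforms", {
  set.seed(11)
  x <- c(rnorm(150, 0.05, 0.02), rnorm(100, 0.35, 0.03), rnorm(120, 0.6, 0.04))
  f1 <- kmeans_1d(x, k = 3, seed = 5)
  f2 <- kmeans_1d(2.5 * x + 0.7, k = 3, seed = 5)
  expect_equal(f2$centroids, 2.5 * f1$centroids + 0.7, tolerance = 1e-8)
  mids1 <- (f1$centroids[-3] + f1$centroids[-1]) / 2
  mids2 <- (f2$centroids[-3] + f2$centroids[-1]) / 2
  expect_identical(findInterval(x, mids1, left.open = TRUE),
                   findInterval(2.5 * x + 0.7, mids2, left.open = TRUE))
})

test_that("k-means is deterministic under a fixed seed", {
  x <- rnorm(500)
  expect_identical(kmeans_1d(x, seed = 3), kmeans_1d(x, seed = 3))
})

test_that("tissue classification assigns nearest centroid with low-tie rule", {
  model <- structure(list(centroids = c(0.1, 0.4, 0.6),
                          class_map = c(lung = 1L, intermediate = 2L,
                                        soft = 3L)),
                     class = "tissue_cluster_model")
  x <- array(0.5, c(4, 4, 8))
  x[1, 1, 1] <- 0.05   # -> lung
  x[2, 1, 1] <- 0.59   # -> soft
  x[3, 1, 1] <- 0.38   # -> intermediate
  x[4, 1, 1] <- 0.25   # exact midpoint of 0.1 and 0.4 -> lung
  m <- array(TRUE, c(4, 4, 8))
  seg <- classify_tissue(ct_volume(x), m, model)
  expect_equal(seg$classes[1, 1, 1], 1L)
  expect_equal(seg$classes[2, 1, 1], 3L)
  expect_equal(seg$classes[3, 1, 1], 2L)
  expect_equal(seg$classes[4, 1, 1], 1L)
  expect_error(classify_tissue(ct_volume(x), array(FALSE, c(4, 4, 8)), model),
               "empty")
})

test_that("in-cavity classification recovers phantom classes", {
  ph <- small_phantom()
  res <- small_result()
  seg <- res$segmentation
  leg <- ph$labels$legend
  m <- res$mask$mask
  # class means are >= 4 noise SDs apart, so per-class recall is high
  for (cls in c("lung", "intermediate", "soft")) {
    truth <- true_class_mask(ph$labels, cls) & m
    pred_code <- seg$legend[[cls]]
    # recall among in-mask voxels of that class still inside the bounds
    inb <- truth & seg$classes > 0L
    if (sum(inb) > 100)
      expect_gt(mean(seg$classes[inb] == pred_code), 0.9)
  }
})
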