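# Center initialization, two-class K-means / FCM, per-cell segmentation.

test_that("initial centers are data-driven and deterministic", {
  img <- discCellImage(21, 13, fg = 9000, bg = 400)
  cell <- cellSpec(1L, 21L, 1L, 21L)
  tpl <- gaussianTemplate(13, 13 / 4)
  fm <- pixelFeatures(img, cell, tpl)
  red <- pcaReduce(fm)
  i1 <- initCenters(fm, red, kBg = 420, cell)
  i2 <- initCenters(fm, red, kBg = 420, cell)
  expect_identical(i1, i2)
  expect_equal(rownames(i1), c("background", "foreground"))
  # the foreground center sits in the spot cloud, the background center
  # in the glass cloud
  disc <- as.vector(discMask(21, 13))
  fgMean <- colMeans(red$Z[disc, , drop = FALSE])
  bgMean <- colMeans(red$Z[!disc, , drop = FALSE])
  dTo <- function(x, y) sqrt(sum((x - y)^2))
  expect_lt(dTo(i1["foreground", ], fgMean), dTo(i1["foreground", ], bgMean))
  expect_lt(dTo(i1["background", ], bgMean), dTo(i1["background", ], fgMean))
})

test_that("K-means solves separable toys in one pass", {
  f <- kmeansTwoClass(matrix(c(0, 0, 10, 10)), matrix(c(0, 10)))
  expect_equal(clusterLabels(f), c(1L, 1L, 2L, 2L))
  expect_equal(as.vector(clusterCenters(f)), c(0, 10))
  expect_equal(f@nIter, 1L)
  # all-identical points collapse to the tie-break cluster
  g <- kmeansTwoClass(matrix(rep(4, 5)), matrix(c(4, 4)))
  expect_true(all(clusterLabels(g) == 1L))
  expect_true(all(clusterCenters(g) == 4))
})

test_that("K-means reaches a verified Lloyd fixed point", {
  set.seed(23)
  for (rep in 1:20) {
    n <- sample(4:12, 1); p <- sample(1:3, 1)
    X <- matrix(rnorm(n * p, sd = 2), n, p)
    init <- X[sample(n, 2), , drop = FALSE]
    f <- kmeansTwoClass(X, init, tol = 1e-12, maxIter = 200)
    lab <- clusterLabels(f)
    ctr <- clusterCenters(f)
    # fixed point: labels are nearest-center, centers are label means
    expect_equal(oracleNearest(X, ctr), lab)
    for (k in 1:2) if (any(lab == k))
      expect_equal(ctr[k, ], colMeans(X[lab == k, , drop = FALSE]),
                   tolerance = 1e-9, ignore_attr = TRUE)
    # objective never increases
    expect_true(all(diff(costTrace(f)) <= 1e-9))
  }
})

test_that("K-means agrees with stats::kmeans from the same start", {
  set.seed(29)
  X <- matrix(c(rnorm(20, 0), rnorm(20, 8)), ncol = 2)
  init <- rbind(X[1, ], X[20, ])
  mine <- kmeansTwoClass(X, init, tol = 1e-12)
  ref <- kmeans(X, centers = init, algorithm = "Lloyd", iter.max = 100)
  expect_equal(unname(sort(clusterCenters(mine)[, 1])),
               unname(sort(ref$centers[, 1])), tolerance = 1e-6)
  expect_equal(tail(costTrace(mine), 1), ref$tot.withinss,
               tolerance = 1e-6)
})

test_that("FCM membership follows Eq 1 with the singularity rule", {
  X <- matrix(c(0, 5, 10))
  init <- matrix(c(0, 10))
  f <- fcmTwoClass(X, init, maxIter = 1L)
  U <- membershipMatrix(f)
  expect_equal(rowSums(U), rep(1, 3))
  expect_equal(U[2, ], c(0.5, 0.5))       # equidistant point
  expect_equal(U[1, ], c(1, 0))           # coincident with center 1
  expect_equal(U[3, ], c(0, 1))           # coincident with center 2
  expect_error(fcmTwoClass(X, init, mFuzz = 1),
               class = "microseg_parameter_error")
})

test_that("FCM converges to the independent fixed-point iterator", {
  set.seed(37)
  for (rep in 1:50) {
    n <- sample(6:30, 1); p <- sample(1:3, 1)
    X <- matrix(rnorm(n * p, sd = 3), n, p)
    init <- X[sample(n, 2), , drop = FALSE]
    f <- fcmTwoClass(X, init, tol = 1e-10, maxIter = 500)
    o <- oracleFcm(X, init, tol = 1e-10, maxIter = 500)
    expect_equal(clusterCenters(f), o$centers, tolerance = 1e-6,
                 ignore_attr = TRUE)
    expect_equal(rowSums(membershipMatrix(f)), rep(1, n),
                 tolerance = 1e-12)
    expect_true(all(diff(costTrace(f)) <= 1e-9))
  }
})

test_that("FCM agrees with e1071::cmeans on a separated dataset", {
  set.seed(43)
  X <- matrix(c(rnorm(25, 0), rnorm(25, 10)), ncol = 1)
  init <- matrix(c(-0.5, 10.5))
  mine <- fcmTwoClass(X, init, tol = 1e-9, maxIter = 500)
  ref <- e1071::cmeans(X, centers = init, m = 2, iter.max = 500,
                       method = "cmeans")
  expect_equal(unname(sort(clusterCenters(mine)[, 1])),
               unname(sort(ref$centers[, 1])), tolerance = 1e-4)
})

test_that("FCM labels approach K-means labels as fuzziness vanishes", {
  set.seed(47)
  X <- matrix(c(rnorm(15, 0, 0.5), rnorm(15, 12, 0.5)))
  init <- matrix(c(1, 11))
  km <- kmeansTwoClass(X, init)
  fc <- fcmTwoClass(X, init, mFuzz = 1.05, maxIter = 300)
  expect_equal(clusterLabels(fc), clusterLabels(km))
})

test_that("cell segmentation recovers a clean spot and stays empty on glass", {
  img <- discCellImage(20, 12)
  cell <- cellSpec(1L, 20L, 1L, 20L)
  tpl <- gaussianTemplate(11, 11 / 4)
  disc <- discMask(20, 12)
  for (mode in c("ikm", "ifcm")) {
    seg <- segmentCell(img, cell, kBg = 500, mode = mode, template = tpl)
    # every disc pixel is recovered; any extras are a thin halo ring
    # adjacent to the disc (window features of neighboring background
    # pixels are spot-contaminated), removed later by the spot circle
    expect_true(all(seg$mask[disc]))
    expect_identical(removeOutsideCircle(seg$mask, c(10.5, 10.5), 12),
                     disc)
  }
  # ikm and ifcm agree on separable data up to the off-spot halo
  a <- segmentCell(img, cell, 500, "ikm", template = tpl)
  b <- segmentCell(img, cell, 500, "ifcm", template = tpl)
  expect_identical(removeOutsideCircle(a$mask, c(10.5, 10.5), 12),
                   removeOutsideCircle(b$mask, c(10.5, 10.5), 12))
  # background-only cell, degenerate initialization path
  flat <- matrix(500, 20, 20)
  segFlat <- segmentCell(flat, cell, kBg = 500, mode = "ikm",
                         template = tpl)
  expect_lte(mean(segFlat$mask), 0.05)
  # improved path is deterministic
  expect_identical(segmentCell(img, cell, 500, "ikm", template = tpl)$mask,
                   a$mask)
  # baselines are seeded-deterministic
  k1 <- segmentCell(img, cell, 500, "km", seed = 5)
  k2 <- segmentCell(img, cell, 500, "km", seed = 5)
  expect_identical(k1$mask, k2$mask)
  expect_error(segmentCell(img, cell, 500, "ikm"),
               class = "microseg_parameter_error")
})
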