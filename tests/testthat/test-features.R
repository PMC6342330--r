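# Gaussian template, shape correlation, per-pixel descriptors, PCA
# fusion.

test_that("gaussian template is peak-normalized and isotropic", {
  t5 <- gaussianTemplate(5, 1)
  expect_equal(t5[3, 3], 1)
  expect_equal(t5, t(t5))
  expect_equal(t5, t5[5:1, 5:1])                 # 180 degrees
  expect_equal(t5, t(t5)[, 5:1][5:1, ][, ])      # 90 degrees
  expect_equal(t5[1, 1], exp(-(2^2 + 2^2) / (2 * 1^2)))
  expect_error(gaussianTemplate(2), class = "microseg_parameter_error")
})

test_that("shape correlation is Pearson against the template", {
  tpl <- gaussianTemplate(3, 1)
  # a window that is an affine image of the template correlates at 1
  img <- oraclePad(2.5 * tpl + 7, 2)
  expect_equal(shapeCorrelation(img, c(3, 3) + 1, tpl), 1)
  imgNeg <- oraclePad(-tpl + 100, 2)
  expect_equal(shapeCorrelation(imgNeg, c(4, 4), tpl), -1)
  # hand-specified window, cor() as the oracle
  win <- matrix(c(1, 2, 1, 2, 4, 2, 1, 2, 1), 3)
  expect_equal(shapeCorrelation(oraclePad(win, 1), c(3, 3), tpl),
               cor(as.vector(win), as.vector(tpl)))
  # constant window -> defined as 0
  expect_equal(shapeCorrelation(matrix(5, 9, 9), c(5, 5), tpl), 0)
  expect_error(shapeCorrelation(matrix(5, 9, 9), c(5, 5),
                                matrix(1, 4, 4)),
               class = "microseg_parameter_error")
})

test_that("shape correlation matches the summation formula per term", {
  set.seed(41)
  tpl <- gaussianTemplate(5, 1.25)
  tv <- as.vector(tpl)
  img <- matrix(runif(900, 0, 65535), 30, 30)
  for (rep in 1:100) {
    i <- sample(3:28, 1); j <- sample(3:28, 1)
    win <- img[(i - 2):(i + 2), (j - 2):(j + 2)]
    wv <- as.vector(win)
    num <- sum((wv - mean(wv)) * (tv - mean(tv)))
    den <- sqrt(sum((wv - mean(wv))^2) * sum((tv - mean(tv))^2))
    expect_equal(shapeCorrelation(img, c(i, j), tpl), num / den,
                 tolerance = 1e-12)
  }
})

test_that("pixel features obey the Table-style definitions", {
  img <- discCellImage(21, 13)        # odd cell: center pixel = center
  cell <- cellSpec(1L, 21L, 1L, 21L)
  tpl <- gaussianTemplate(13, 13 / 4)
  fm <- pixelFeatures(img, cell, tpl)
  expect_equal(colnames(fm$F),
               c("r", "i", "j", "D_M", "D_Eud", "I", "Ibar", "delta", "E"))
  # center pixel: zero distances, intensity = fg
  ctr <- fm$centerIndex
  expect_equal(unname(fm$F[ctr, "D_M"]), 0)
  expect_equal(unname(fm$F[ctr, "D_Eud"]), 0)
  expect_equal(unname(fm$F[ctr, "I"]), 10000)
  # city-block dominates Euclidean everywhere; r bounded; delta, E >= 0
  expect_true(all(fm$F[, "D_M"] >= fm$F[, "D_Eud"] - 1e-12))
  expect_true(all(abs(fm$F[, "r"]) <= 1 + 1e-12))
  expect_true(all(fm$F[, "delta"] >= 0))
  expect_true(all(fm$F[, "E"] >= 0))
  # constant cell: no texture anywhere
  flat <- pixelFeatures(matrix(300, 15, 15), cellSpec(1L, 15L, 1L, 15L),
                        gaussianTemplate(5, 1))
  expect_true(all(flat$F[, "delta"] == 0))
  expect_true(all(flat$F[, "E"] == 0))
  expect_true(all(flat$F[, "r"] == 0))
})

test_that("window entropy equals the histogram formula", {
  # center 3x3 window: five pixels in one 256-wide bin, four in another
  img <- matrix(100, 5, 5)
  img[2, 2:4] <- 40000; img[3, 2] <- 40000
  cell <- cellSpec(1L, 5L, 1L, 5L)
  fm <- pixelFeatures(img, cell, gaussianTemplate(3, 1))
  ctr <- which(fm$pixels[, 1] == 3 & fm$pixels[, 2] == 3)
  expected <- (5 / 9) * log2(9 / 5) + (4 / 9) * log2(9 / 4)
  expect_equal(unname(fm$F[ctr, "E"]), expected, tolerance = 1e-12)
})

test_that("features are translation-covariant", {
  set.seed(77)
  patch <- matrix(runif(400, 0, 65535), 20, 20)
  img <- matrix(1000, 60, 60)
  img[6:25, 6:25] <- patch
  img[31:50, 36:55] <- patch
  tpl <- gaussianTemplate(7, 1.75)
  fa <- pixelFeatures(img, cellSpec(6L, 25L, 6L, 25L), tpl)
  fb <- pixelFeatures(img, cellSpec(31L, 50L, 36L, 55L), tpl)
  expect_equal(fb$F[, "i"], fa$F[, "i"] + 25)
  expect_equal(fb$F[, "j"], fa$F[, "j"] + 30)
  for (col in c("r", "D_M", "D_Eud", "I", "Ibar", "delta", "E"))
    expect_equal(fb$F[, col], fa$F[, col], tolerance = 1e-12)
})

test_that("PCA fusion standardizes, orders and signs components", {
  set.seed(55)
  n <- 200
  base <- matrix(rnorm(n * 3), n, 3)
  F <- sweep(cbind(base, base, base), 2, rep(c(3, 1, 10), 3), "*")
  red <- pcaReduce(F)
  expect_equal(red$explainedFraction, 1, tolerance = 1e-10)
  expect_equal(dim(red$Z), c(n, 3L))
  # scores: zero mean, uncorrelated, variances = leading eigenvalues
  expect_equal(colMeans(red$Z), rep(0, 3), tolerance = 1e-12)
  cv <- crossprod(red$Z) / (n - 1)
  expect_equal(cv, diag(red$eigenvalues[1:3]), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_true(all(diff(red$eigenvalues) <= 1e-12))
  # deterministic sign: largest-magnitude loading positive
  for (k in 1:3) {
    ld <- red$loadings[, k]
    expect_gt(ld[which.max(abs(ld))], 0)
  }
  # agreement with prcomp on standardized data
  pr <- prcomp(F, center = TRUE, scale. = TRUE)
  expect_equal(red$eigenvalues, pr$sdev^2, tolerance = 1e-8)
  expect_equal(abs(red$Z), abs(pr$x[, 1:3]), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_error(pcaReduce(F[1:9, ]), class = "microseg_insufficient_data")
})

test_that("isotropic inputs spread variance evenly across components", {
  set.seed(91)
  F <- matrix(rnorm(5000 * 9), 5000, 9)
  red <- pcaReduce(F)
  expect_lt(abs(red$explainedFraction - 3 / 9), 0.03)
  expect_lt(max(red$eigenvalues) / min(red$eigenvalues), 1.4)
})

test_that("zero-variance columns are dropped, degenerate cells survive", {
  set.seed(12)
  F <- cbind(rnorm(50), 7, rnorm(50), 0, rnorm(50), 1, 2, 3, 4)
  red <- pcaReduce(F)
  expect_equal(sum(red$keep), 3)
  expect_equal(red$explainedFraction, 1, tolerance = 1e-10)
  # all-constant features: zero scores, fraction defined as 1
  redFlat <- pcaReduce(matrix(5, 40, 9))
  expect_equal(redFlat$Z, matrix(0, 40, 3))
  expect_equal(redFlat$explainedFraction, 1)
})
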