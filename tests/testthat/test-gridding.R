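# Projection profiles, reconstruction filtering, between-class
# thresholding, line extraction/revision, and full-image gridding.

test_that("projection profiles are axis sums", {
  expect_equal(projectionProfile(matrix(3, 4, 7), "rows"), rep(21, 4))
  expect_equal(projectionProfile(matrix(3, 4, 7), "cols"), rep(12, 7))
  img <- matrix(1, 5, 9); img[, 4] <- 50
  pc <- projectionProfile(img, "cols")
  expect_equal(which.max(pc), 4)
  # toy raster vs loop-summed oracle
  set.seed(13)
  toy <- matrix(sample(0:99, 16), 4, 4)
  byHand <- vapply(1:4, function(i) sum(toy[i, ]), numeric(1))
  expect_equal(projectionProfile(toy, "rows"), byHand)
})

test_that("reconstruction filter equals the iterative-dilation oracle", {
  set.seed(31)
  for (i in 1:10) {
    sig <- cumsum(rnorm(30))
    for (drop in c(0.1, 0.3, 0.6))
      expect_equal(reconstructFilter(sig, drop),
                   oracleReconstruct(sig, drop))
  }
  # peaks shorter than the drop are flattened, dominant peaks survive
  sig <- c(0, 0, 10, 10, 0, 0, 2, 0, 0)
  out <- reconstructFilter(sig, 0.3)   # drop = 3 exceeds the small peak
  expect_equal(out, oracleReconstruct(sig, 0.3))
  expect_equal(out[7], out[6])         # small peak gone
  expect_gte(out[3], 7)                # dominant peak retained
  expect_true(all(out <= sig))
  # constant signal passes through unchanged (range 0 => zero drop)
  expect_equal(reconstructFilter(rep(4, 10), 0.3), rep(4, 10))
  expect_error(reconstructFilter(sig, 0), class = "microseg_parameter_error")
  expect_error(reconstructFilter(sig, 1), class = "microseg_parameter_error")
  expect_error(reconstructFilter(c(1, 2), 0.3),
               class = "microseg_parameter_error")
})

test_that("between-class threshold matches the exhaustive sweep", {
  expect_equal(betweenClassThreshold(c(rep(1, 50), rep(9, 50))), 9)
  expect_equal(betweenClassThreshold(c(0, 0, 0, 10, 10, 10)), 10)
  set.seed(17)
  for (i in 1:20) {
    sig <- sample(0:6, 40, replace = TRUE) * 10
    if (length(unique(sig)) < 2) next
    expect_equal(betweenClassThreshold(sig), oracleOtsu(sig))
  }
  expect_error(betweenClassThreshold(rep(3, 10)),
               class = "microseg_degenerate_threshold")
})

test_that("grid lines come from gap midpoints, boundaries from bands", {
  # single central gap at samples 10..14 -> line at the midpoint 12
  sig <- rep(9, 20); sig[10:14] <- 0
  gl <- extractGridLines(sig, 5)
  expect_equal(gl$lines, 12)
  expect_equal(gl$bounds, c(0.5, 9.5, 14.5, 20.5))
  # leading/trailing gaps give only boundary lines
  sig2 <- c(0, 0, 9, 9, 9, 0, 0, 0, 9, 9, 0)
  gl2 <- extractGridLines(sig2, 5)
  expect_equal(gl2$lines, 7)
  expect_equal(gl2$bounds, c(2.5, 5.5, 8.5, 10.5))
  expect_error(extractGridLines(rep(9, 5), 5), class = "microseg_no_gap")
  expect_error(extractGridLines(rep(1, 5), 5), class = "microseg_no_gap")
})

test_that("gap trimming reassigns faint band shoulders to the band", {
  # band shoulders at 4 fall below the threshold 6 but well above the
  # gap floor 0; trimming restores the full band extent
  sig <- c(0, 0, 4, 9, 9, 4, 0, 0, 4, 9, 9, 4, 0, 0)
  raw <- extractGridLines(sig, 6, bandFrac = 0)
  trimmed <- extractGridLines(sig, 6, bandFrac = 0.25)
  expect_equal(raw$bounds, c(3.5, 5.5, 9.5, 11.5))
  expect_equal(trimmed$bounds, c(2.5, 6.5, 8.5, 12.5))
  expect_equal(trimmed$lines, 7.5)
  expect_error(extractGridLines(sig, 6, bandFrac = 1.2),
               class = "microseg_parameter_error")
})

test_that("grid revision restores deleted lines and merges duplicates", {
  lines <- seq(10, 90, by = 20)
  expect_equal(reviseGrid(lines), lines)
  # deleting an interior line leaves a double gap; revision restores it
  expect_equal(reviseGrid(lines[-3]), lines)
  # near-duplicate lines merge to their midpoint
  expect_equal(reviseGrid(sort(c(lines, 50.8))),
               c(10, 30, 50.4, 70, 90))
  expect_warning(out <- reviseGrid(42), "skipped")
  expect_equal(out, 42)
})

test_that("noise-free gridding recovers the generator lattice", {
  p <- synthParams(nRows = 5, nCols = 6, noiseSigma = 0, seed = 2)
  sg <- generateSubgrid(p)
  g <- gridImage(denoiseMedian(cy3Image(sg) + cy5Image(sg)))
  expect_equal(length(hLines(g)), 4)
  expect_equal(length(vLines(g)), 5)
  expect_lte(max(abs(hLines(g) - hLines(sg))), 1)
  expect_lte(max(abs(vLines(g) - vLines(sg))), 1)
  expect_equal(spotDiameter(g), 20)    # d equals the true pitch
  expect_equal(spotSize(g), 12)        # all boundary widths equal 12

  # boundary lines pair up; widths are positive
  b <- boundaryLines(g)
  expect_equal(length(b$h) %% 2, 0)
  expect_equal(length(b$v) %% 2, 0)

  # cells tile the image: disjoint spans covering every pixel
  cells <- gridCells(g)
  expect_equal(nrow(cells), 30)
  cov <- matrix(0L, 100, 120)
  for (i in seq_len(nrow(cells)))
    cov[cells$r0[i]:cells$r1[i], cells$c0[i]:cells$c1[i]] <-
      cov[cells$r0[i]:cells$r1[i], cells$c0[i]:cells$c1[i]] + 1L
  expect_true(all(cov == 1L))
  expect_true(all(cells$rc >= cells$r0 & cells$rc <= cells$r1))
  expect_true(all(cells$cc >= cells$c0 & cells$cc <= cells$c1))
})

test_that("d and s are invariant under pattern translation", {
  p <- synthParams(nRows = 4, nCols = 4, noiseSigma = 0, seed = 6)
  sg <- generateSubgrid(p)
  img <- cy3Image(sg) + cy5Image(sg)
  g0 <- gridImage(img)
  # embed the same pattern shifted inside a larger background canvas
  big <- matrix(2 * 500, 104, 109)
  big[13:92, 22:101] <- img
  g1 <- gridImage(big)
  expect_equal(spotDiameter(g1), spotDiameter(g0))
  expect_equal(spotSize(g1), spotSize(g0))
  expect_equal(hLines(g1) - 12, hLines(g0))
  expect_equal(vLines(g1) - 21, vLines(g0))
})
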