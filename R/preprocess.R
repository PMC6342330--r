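# Image preprocessing: fourth-moment contrast score, border-window
# background gray-level estimation, the piecewise contrast-enhancement
# rule, and 2-D median denoising.

#' Fourth-moment contrast score
#'
#' Computes `C = Sd / (Fom / Mse^2)^(1/4)` over all pixels, where `Mse` is
#' the mean squared deviation from the image mean, `Sd = sqrt(Mse)` and
#' `Fom` is the fourth central moment. `C` is the standard deviation
#' deflated by the fourth root of the kurtosis, so it grows with
#' foreground/background separation and scales linearly with the
#' intensities.
#'
#' @param img numeric intensity matrix.
#' @return a list of class `ContrastStats`: `C`, `Sd`, `Mse`, `Fom`,
#'   `meanP`, `N`.
#' @examples
#' contrastScore(matrix(c(0, 0, 10, 10), 2))$C
#' @export
contrastScore <- function(img) {
  assertMatrixImage(img)
  N <- length(img)
  meanP <- mean(img)
  dev <- img - meanP
  Mse <- sum(dev^2) / N
  if (Mse == 0)
    msgStop("microseg_degenerate_contrast",
            "constant image: contrast score is undefined (Mse = 0)")
  Fom <- sum(dev^4) / N
  Sd <- sqrt(Mse)
  structure(list(C = Sd / (Fom / Mse^2)^(1 / 4),
                 Sd = Sd, Mse = Mse, Fom = Fom, meanP = meanP, N = N),
            class = "ContrastStats")
}

# All admissible top-left window positions whose bounding box intersects
# the border band (band width = windowSize) of an nr x nc image.
#' @noRd
borderWindowPositions <- function(nr, nc, windowSize) {
  if (nr < 2L * windowSize || nc < 2L * windowSize)
    msgStop("microseg_parameter_error",
            "image (%d x %d) too small for %d-pixel border windows",
            nr, nc, windowSize)
  rmax <- nr - windowSize + 1L
  cmax <- nc - windowSize + 1L
  band <- windowSize
  pos <- expand.grid(r = seq_len(rmax), c = seq_len(cmax))
  touch <- pos$r <= band | pos$c <= band |
    (pos$r + windowSize - 1L) >= (nr - band + 1L) |
    (pos$c + windowSize - 1L) >= (nc - band + 1L)
  pos[touch, , drop = FALSE]
}

#' Estimate the background gray level from border windows
#'
#' Per trial, draws `windowsPerTrial` square windows whose bounding boxes
#' touch the image border band, records the maximum intensity of each,
#' and keeps the minimum of those maxima; the estimate `k` is the mean of
#' this min-of-max statistic over `m` trials. The result is an upper
#' quantile of the border background — a background ceiling rather than a
#' background mean (for Gaussian noise it sits roughly two noise standard
#' deviations above the background level).
#'
#' @param img numeric intensity matrix, at least `2*windowSize` pixels on
#'   each side.
#' @param m number of repeated trials (default 10).
#' @param windowsPerTrial windows drawn per trial (default 12).
#' @param windowSize window side length in pixels (default 10).
#' @param seed RNG seed for the window draws.
#' @return the scalar estimate `k`.
#' @examples
#' estimateBackground(matrix(7, 40, 40), seed = 1)
#' @export
estimateBackground <- function(img, m = 10L, windowsPerTrial = 12L,
                               windowSize = 10L, seed = NULL) {
  assertMatrixImage(img)
  pos <- borderWindowPositions(nrow(img), ncol(img), windowSize)
  withSeed(seed, {
    trialMins <- vapply(seq_len(m), function(i) {
      take <- sample.int(nrow(pos), windowsPerTrial, replace = TRUE)
      maxima <- vapply(take, function(t) {
        r <- pos$r[t]; cc <- pos$c[t]
        max(img[r:(r + windowSize - 1L), cc:(cc + windowSize - 1L)])
      }, numeric(1))
      min(maxima)
    }, numeric(1))
    mean(trialMins)
  })
}

#' Piecewise contrast enhancement
#'
#' Multiplies every pixel at or below the background gray level `k` by
#' `target / C` and leaves brighter pixels unchanged, clipping the result
#' to the 16-bit range. `branch = "gt"` applies the multiplier to the
#' opposite branch (pixels above `k`) instead.
#'
#' Note the rule is a near-uniform rescale whenever the image's dynamic
#' range lies at or below `k` (the low-contrast regime it is meant for);
#' when `k` falls inside the foreground intensity distribution it is
#' non-monotone across the branch seam — see the package vignette for why
#' the default pipeline keeps it out of the gridding path.
#'
#' @param img numeric intensity matrix.
#' @param C contrast score of `img` (must be positive).
#' @param k background gray level splitting the two branches.
#' @param target target contrast score (default 10000).
#' @param branch which branch is multiplied: `"le"` (pixels `<= k`,
#'   default) or `"gt"`.
#' @return enhanced image matrix.
#' @examples
#' enhanceContrast(matrix(c(2, 20), 1), C = 5000, k = 10)
#' @export
enhanceContrast <- function(img, C, k, target = 10000,
                            branch = c("le", "gt")) {
  assertMatrixImage(img)
  branch <- match.arg(branch)
  if (!is.numeric(C) || length(C) != 1L || C <= 0)
    msgStop("microseg_parameter_error", "contrast score C must be > 0")
  sel <- if (branch == "le") img <= k else img > k
  out <- img
  out[sel] <- pmin(pmax(img[sel] * (target / C), 0), 65535)
  out
}

#' 2-D median filter with edge replication
#'
#' Standard square-window median filter; edges are handled by replicating
#' the border pixels. The 3x3 case uses an exact median-of-9 exchange
#' network, larger odd windows fall back to per-pixel sorting.
#'
#' @param img numeric intensity matrix.
#' @param size odd window side length, `>= 3`.
#' @return filtered matrix of the same shape.
#' @examples
#' m <- matrix(0, 5, 5); m[3, 3] <- 100
#' max(denoiseMedian(m))
#' @export
denoiseMedian <- function(img, size = 3L) {
  assertMatrixImage(img)
  size <- as.integer(size)
  if (size < 3L || size %% 2L == 0L)
    msgStop("microseg_parameter_error",
            "median window size must be odd and >= 3 (got %d)", size)
  half <- (size - 1L) %/% 2L
  W <- windowStack(img, half)
  med <- if (size == 3L) rowMedian9(W) else apply(W, 1L, median)
  matrix(med, nrow(img), ncol(img))
}

#' Preprocess one intensity raster
#'
#' Convenience chain: contrast score, background estimate, optional
#' contrast enhancement, median denoising. Returns the processed raster
#' together with the computed scalars.
#'
#' @param img numeric intensity matrix.
#' @param medianSize median filter window (odd, `>= 3`).
#' @param applyEnhancement apply [enhanceContrast()] before denoising?
#' @param target,branch passed to [enhanceContrast()].
#' @param m,windowsPerTrial,windowSize,seed passed to
#'   [estimateBackground()].
#' @return list with `img` (processed raster), `C` (contrast stats list)
#'   and `k` (background estimate).
#' @export
preprocessImage <- function(img, medianSize = 3L, applyEnhancement = FALSE,
                            target = 10000, branch = "le",
                            m = 10L, windowsPerTrial = 12L,
                            windowSize = 10L, seed = NULL) {
  cs <- contrastScore(img)
  k <- estimateBackground(img, m = m, windowsPerTrial = windowsPerTrial,
                          windowSize = windowSize, seed = seed)
  out <- if (applyEnhancement)
    enhanceContrast(img, cs$C, k, target = target, branch = branch)
  else img
  list(img = denoiseMedian(out, medianSize), C = cs, k = k)
}
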