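# Per-pixel features for one spot cell and their PCA fusion. Each pixel
# carries a 9-vector [r, i, j, D_M, D_Eud, I, Ibar, delta, E]: the
# Pearson correlation r of its d x d neighborhood with an isotropic
# Gaussian spot template (shape), its absolute coordinates and city-block
# / Euclidean distances to the cell center (spatial), and its intensity,
# 3x3 local mean, 3x3 local squared deviation and 3x3 local histogram
# entropy (intensity/texture). Features are z-scored and fused to the
# top three principal components before clustering.

FEATURE_NAMES <- c("r", "i", "j", "D_M", "D_Eud", "I", "Ibar",
                   "delta", "E")

#' Isotropic Gaussian spot template
#'
#' A `d x d` Gaussian centered at the template midpoint with peak value
#' 1, used as the theoretical spot profile for the shape-correlation
#' feature.
#'
#' @param d template side length (pixels, `>= 3`; odd so the template
#'   centers on a pixel).
#' @param sigma Gaussian standard deviation in pixels (default `d / 4`).
#' @return `d x d` numeric matrix with 1 at the center.
#' @examples
#' gaussianTemplate(5, 1)[3, 3]
#' @export
gaussianTemplate <- function(d, sigma = d / 4) {
  d <- as.integer(d)
  if (d < 3L)
    msgStop("microseg_parameter_error",
            "template size d must be >= 3 (got %d)", d)
  ctr <- (d + 1) / 2
  ii <- matrix(seq_len(d), d, d)
  jj <- t(ii)
  exp(-((ii - ctr)^2 + (jj - ctr)^2) / (2 * sigma^2))
}

# Vectorized Pearson correlation of every row of a window stack with a
# fixed template vector; zero-variance windows give 0.
#' @noRd
stackCorrelation <- function(W, tvec) {
  tc <- tvec - mean(tvec)
  tss <- sum(tc^2)
  wc <- W - rowMeans(W)
  num <- as.vector(wc %*% tc)
  wss <- rowSums(wc^2)
  den <- sqrt(wss * tss)
  r <- ifelse(den > 0, num / den, 0)
  attr(r, "nZeroVar") <- sum(den == 0)
  r
}

#' Shape correlation of one pixel's neighborhood with a spot template
#'
#' Pearson correlation coefficient between the odd-sized template and the
#' equally sized window centered on the pixel (edge-replicated at image
#' borders). A zero-variance window (or template) yields 0.
#'
#' @param img numeric intensity matrix.
#' @param pixel integer `c(i, j)` position (1-based).
#' @param template odd-sized square template, e.g. [gaussianTemplate()].
#' @return correlation in `[-1, 1]`.
#' @export
shapeCorrelation <- function(img, pixel, template) {
  assertMatrixImage(img)
  d <- nrow(template)
  if (d %% 2L == 0L || d != ncol(template))
    msgStop("microseg_parameter_error",
            "template must be square with odd side length")
  half <- (d - 1L) %/% 2L
  p <- padReplicate(img, half)
  win <- p[(pixel[1L]):(pixel[1L] + 2L * half),
           (pixel[2L]):(pixel[2L] + 2L * half)]
  r <- stackCorrelation(matrix(as.vector(win), 1L), as.vector(template))
  as.numeric(r)
}

#' Per-pixel feature matrix for one spot cell
#'
#' Builds the 9-column descriptor for every pixel of the cell. Local
#' windows (template-sized for `r`, 3x3 for `Ibar`, `delta` and `E`) are
#' taken from the cell raster with edge replication; `delta` is the mean
#' squared deviation of the 3x3 window and `E` the base-2 Shannon entropy
#' of its binned histogram (`entropyBins` equal-width bins over the
#' 16-bit range). Distances are measured to the cell's exact geometric
#' center (half-integer for even-sized cells), keeping the spatial
#' features symmetric about the spot.
#'
#' @param img full-image intensity raster.
#' @param cell one row of a [SpotGrid-class] cell table (fields `r0`,
#'   `r1`, `c0`, `c1`, `rc`, `cc`), or any list with those fields.
#' @param template odd-sized Gaussian template for the shape feature.
#' @param entropyBins number of histogram bins for `E` (default 256,
#'   i.e. 16-bit values right-shifted by 8; use 65536 for full depth).
#' @return a `FeatureMatrix` list: `F` (n x 9 matrix), `pixels` (n x 2
#'   absolute coordinates), `centerIndex` (row of the cell-center pixel).
#' @export
pixelFeatures <- function(img, cell, template, entropyBins = 256L) {
  assertMatrixImage(img)
  rows <- cell$r0:cell$r1
  cols <- cell$c0:cell$c1
  if (min(rows) < 1L || max(rows) > nrow(img) ||
      min(cols) < 1L || max(cols) > ncol(img))
    msgStop("microseg_parameter_error", "cell lies outside the image")
  cellImg <- img[rows, cols, drop = FALSE]
  nr <- length(rows); nc <- length(cols)
  ii <- matrix(rows, nr, nc)
  jj <- matrix(cols, nr, nc, byrow = TRUE)

  dHalf <- (nrow(template) - 1L) %/% 2L
  r <- stackCorrelation(windowStack(cellImg, dHalf), as.vector(template))

  W9 <- windowStack(cellImg, 1L)
  Ibar <- rowMeans(W9)
  delta <- rowMeans((W9 - Ibar)^2)
  binWidth <- 65536 / entropyBins
  B <- floor(W9 / binWidth)
  cnt <- matrix(0, nrow(B), 9L)
  for (a in 1:9)
    for (b in 1:9)
      cnt[, a] <- cnt[, a] + (B[, a] == B[, b])
  E <- rowMeans(log2(9 / cnt))

  icExact <- (cell$r0 + cell$r1) / 2
  jcExact <- (cell$c0 + cell$c1) / 2
  F <- cbind(
    r = as.numeric(r),
    i = as.vector(ii), j = as.vector(jj),
    D_M = abs(as.vector(ii) - icExact) + abs(as.vector(jj) - jcExact),
    D_Eud = sqrt((as.vector(ii) - icExact)^2 +
                 (as.vector(jj) - jcExact)^2),
    I = as.vector(cellImg), Ibar = Ibar, delta = delta, E = E)
  centerIndex <- which(as.vector(ii) == cell$rc &
                       as.vector(jj) == cell$cc)
  structure(list(F = F, pixels = cbind(i = as.vector(ii),
                                       j = as.vector(jj)),
                 centerIndex = centerIndex[1L]),
            class = "FeatureMatrix")
}

#' Fuse features to principal components
#'
#' Z-scores each feature column (zero-variance columns are dropped),
#' eigendecomposes the covariance of the standardized matrix, and returns
#' scores on the leading `nComponents` eigenvectors. Eigenvector signs
#' follow a deterministic convention (the largest-magnitude loading of
#' each component is positive). When fewer informative columns than
#' `nComponents` survive, the missing score columns are zero.
#'
#' @param F a `FeatureMatrix` from [pixelFeatures()] or a plain numeric
#'   matrix with more rows than columns.
#' @param nComponents number of components to keep (default 3).
#' @return a `ReducedFeatures` list: `Z` (n x nComponents scores),
#'   `eigenvalues` (all, descending), `explainedFraction`, `loadings`,
#'   `center`, `scale`, `keep` (columns retained).
#' @export
pcaReduce <- function(F, nComponents = 3L) {
  X <- if (inherits(F, "FeatureMatrix")) F$F else F
  if (!is.matrix(X))
    msgStop("microseg_parameter_error", "F must be a feature matrix")
  n <- nrow(X); p <- ncol(X)
  if (n <= p)
    msgStop("microseg_insufficient_data",
            "PCA needs more pixels (%d) than features (%d)", n, p)
  ctr <- colMeans(X)
  scl <- apply(X, 2L, sd)
  keep <- scl > 1e-12 * pmax(1, abs(ctr))
  nKeep <- sum(keep)
  if (nKeep == 0L) {
    return(structure(list(
      Z = matrix(0, n, nComponents),
      eigenvalues = numeric(), explainedFraction = 1,
      loadings = matrix(0, 0L, nComponents),
      center = ctr, scale = scl, keep = keep),
      class = "ReducedFeatures"))
  }
  Z0 <- sweep(sweep(X[, keep, drop = FALSE], 2L, ctr[keep]),
              2L, scl[keep], "/")
  S <- crossprod(Z0) / (n - 1)
  eig <- eigen(S, symmetric = TRUE)
  lam <- pmax(eig$values, 0)
  V <- eig$vectors
  take <- min(nComponents, nKeep)
  for (kk in seq_len(take)) {
    imax <- which.max(abs(V[, kk]))
    if (V[imax, kk] < 0) V[, kk] <- -V[, kk]
  }
  loadings <- matrix(0, nKeep, nComponents,
                     dimnames = list(colnames(Z0), NULL))
  loadings[, seq_len(take)] <- V[, seq_len(take), drop = FALSE]
  Z <- Z0 %*% loadings
  structure(list(
    Z = Z, eigenvalues = lam,
    explainedFraction = if (sum(lam) > 0)
      sum(lam[seq_len(take)]) / sum(lam) else 1,
    loadings = loadings, center = ctr, scale = scl, keep = keep),
    class = "ReducedFeatures")
}

# Project one raw 9-vector through a fitted ReducedFeatures transform.
#' @noRd
projectFeatures <- function(red, raw) {
  if (!any(red$keep)) return(rep(0, ncol(red$Z)))
  z <- (raw[red$keep] - red$center[red$keep]) / red$scale[red$keep]
  as.vector(z %*% red$loadings)
}
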