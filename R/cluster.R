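# Two-class clustering of spot-cell pixels. The improved variants (ikm,
# ifcm) run on the PCA-fused features with data-driven initial centers:
# the background center is the reduced feature vector of the pixel whose
# intensity is nearest the estimated background gray level k, the
# foreground center the cell-center pixel's features with its intensity
# entry replaced by the 3x3 center-window mean. The plain baselines (km,
# fcm) use the sole pixel intensity and seeded random-pixel
# initialization. Cluster 1 is always the background-initialized one;
# ties in assignment or membership resolve to it.

#' Data-driven initial cluster centers for one spot cell
#'
#' @param features `FeatureMatrix` from [pixelFeatures()].
#' @param reduced matching `ReducedFeatures` from [pcaReduce()].
#' @param kBg estimated background gray level (from
#'   [estimateBackground()]).
#' @param cell the cell row (needs `r0`, `r1`, `c0`, `c1` for the
#'   corner tie-break).
#' @return 2 x nComponents matrix; row 1 = background center, row 2 =
#'   foreground center. Fully deterministic.
#' @export
initCenters <- function(features, reduced, kBg, cell) {
  F <- features$F
  Ivec <- F[, "I"]
  dk <- abs(Ivec - kBg)
  cand <- which(dk == min(dk))
  if (length(cand) > 1L) {
    px <- features$pixels[cand, , drop = FALSE]
    corners <- rbind(c(cell$r0, cell$c0), c(cell$r0, cell$c1),
                     c(cell$r1, cell$c0), c(cell$r1, cell$c1))
    cornerDist <- apply(px, 1L, function(p)
      min(sqrt((corners[, 1L] - p[1L])^2 + (corners[, 2L] - p[2L])^2)))
    cand <- cand[which.min(cornerDist)]
  }
  bg <- reduced$Z[cand[1L], ]
  raw <- F[features$centerIndex, ]
  raw["I"] <- raw["Ibar"]   # 3x3 center-window mean
  fg <- projectFeatures(reduced, raw)
  out <- rbind(background = bg, foreground = fg)
  colnames(out) <- NULL
  out
}

#' @noRd
clusterDistances <- function(X, centers) {
  cbind(rowSums(sweep(X, 2L, centers[1L, ])^2),
        rowSums(sweep(X, 2L, centers[2L, ])^2))
}

#' Two-class K-means from fixed initial centers
#'
#' Lloyd iterations: nearest-center assignment (squared Euclidean, ties
#' to cluster 1) alternating with center recomputation, until the maximum
#' center movement falls below `tol` or `maxIter` is reached. A cluster
#' left empty is re-seeded at the point farthest from the other center.
#'
#' @param X numeric matrix of observations (rows).
#' @param init 2 x p matrix of initial centers.
#' @param tol termination threshold on the largest absolute center
#'   coordinate movement (default 1e-5).
#' @param maxIter iteration cap (default 100).
#' @return a [ClusterFit-class] (no membership matrix).
#' @examples
#' f <- kmeansTwoClass(matrix(c(0, 0, 10, 10)), matrix(c(0, 10)))
#' clusterLabels(f)
#' @export
kmeansTwoClass <- function(X, init, tol = 1e-5, maxIter = 100L) {
  X <- as.matrix(X)
  if (nrow(X) < 2L)
    msgStop("microseg_parameter_error", "need at least 2 observations")
  centers <- as.matrix(init)
  cost <- numeric()
  iter <- 0L
  repeat {
    iter <- iter + 1L
    D <- clusterDistances(X, centers)
    lab <- ifelse(D[, 1L] <= D[, 2L], 1L, 2L)
    newC <- centers
    for (k in 1:2) {
      if (any(lab == k)) {
        newC[k, ] <- colMeans(X[lab == k, , drop = FALSE])
      } else {
        far <- which.max(D[, 3L - k])
        newC[k, ] <- X[far, ]
      }
    }
    cost <- c(cost, sum(clusterDistances(X, newC)[cbind(seq_along(lab),
                                                        lab)]))
    moved <- max(abs(newC - centers))
    centers <- newC
    if (moved < tol || iter >= maxIter) break
  }
  D <- clusterDistances(X, centers)
  lab <- ifelse(D[, 1L] <= D[, 2L], 1L, 2L)
  new("ClusterFit", labels = lab, centers = centers, membership = NULL,
      costTrace = cost, nIter = iter, mode = "km")
}

#' @noRd
fcmMembership <- function(D2, mFuzz) {
  e <- 1 / (mFuzz - 1)
  inv <- (1 / D2)^e
  U <- inv / rowSums(inv)
  zero <- D2 == 0
  hasZero <- rowSums(zero) > 0
  if (any(hasZero)) {
    U[hasZero, ] <- 0
    # coincident pixel: crisp membership; double-zero resolves to bg
    U[hasZero, 1L] <- ifelse(zero[hasZero, 1L], 1, 0)
    U[hasZero, 2L] <- 1 - U[hasZero, 1L]
  }
  U
}

#' Two-class fuzzy C-means from fixed initial centers
#'
#' Alternates the membership update
#' `u_ij = 1 / sum_k (d_ij / d_kj)^(2/(m-1))` with the weighted center
#' update `c_i = sum_j u_ij^m x_j / sum_j u_ij^m`, terminating when the
#' largest absolute center movement drops below `tol` or at `maxIter`.
#' The objective `J = sum_ij u_ij^m d_ij^2` is recorded per iteration and
#' is non-increasing. A pixel coincident with a center receives crisp
#' membership for that center. Labels are the membership argmax, ties to
#' the background cluster.
#'
#' @param X numeric matrix of observations (rows).
#' @param init 2 x p matrix of initial centers.
#' @param mFuzz fuzziness exponent m, `> 1` (default 2).
#' @param tol termination threshold on center movement (default 1e-5).
#' @param maxIter iteration cap (default 100).
#' @return a [ClusterFit-class] with membership matrix.
#' @examples
#' f <- fcmTwoClass(matrix(c(0, 0.1, 9.9, 10)), matrix(c(0, 10)))
#' membershipMatrix(f)[1, ]
#' @export
fcmTwoClass <- function(X, init, mFuzz = 2, tol = 1e-5, maxIter = 100L) {
  X <- as.matrix(X)
  if (nrow(X) < 2L)
    msgStop("microseg_parameter_error", "need at least 2 observations")
  if (mFuzz <= 1)
    msgStop("microseg_parameter_error", "mFuzz must be > 1")
  centers <- as.matrix(init)
  cost <- numeric()
  iter <- 0L
  U <- NULL
  repeat {
    iter <- iter + 1L
    D2 <- clusterDistances(X, centers)
    U <- fcmMembership(D2, mFuzz)
    Um <- U^mFuzz
    newC <- centers
    for (k in 1:2) {
      wk <- sum(Um[, k])
      if (wk > 0) newC[k, ] <- colSums(Um[, k] * X) / wk
    }
    cost <- c(cost, sum(Um * clusterDistances(X, newC)))
    moved <- max(abs(newC - centers))
    centers <- newC
    if (moved < tol || iter >= maxIter) break
  }
  lab <- ifelse(U[, 1L] >= U[, 2L], 1L, 2L)
  new("ClusterFit", labels = lab, centers = centers, membership = U,
      costTrace = cost, nIter = iter, mode = "fcm")
}

#' Segment one spot cell
#'
#' Runs the selected clustering mode on the cell's pixels and returns a
#' foreground mask. The improved modes (`ikm`, `ifcm`) extract the
#' 9-feature descriptor, fuse it with PCA and start from the data-driven
#' centers; the baselines (`km`, `fcm`) cluster the sole pixel intensity
#' from two seeded random pixels. The foreground cluster is the one with
#' the higher mean raw intensity; if the foreground-initialized cluster
#' ends up empty the cell has no foreground (the degenerate-initialization
#' path for background-only cells), and if the background cluster is
#' empty the whole cell is foreground (left to the refinement step to
#' flag).
#'
#' @param img intensity raster used for clustering (typically the
#'   denoised channel sum).
#' @param cell one cell row of a [SpotGrid-class].
#' @param kBg background gray-level estimate.
#' @param mode `"ikm"`, `"ifcm"`, `"km"` or `"fcm"`.
#' @param template Gaussian template (improved modes).
#' @param mFuzz,tol,maxIter clustering controls.
#' @param entropyBins histogram bins for the entropy feature.
#' @param seed RNG seed for the baseline random initialization.
#' @return list with `mask` (logical cell matrix) and `fit`
#'   ([ClusterFit-class]).
#' @export
segmentCell <- function(img, cell, kBg,
                        mode = c("ikm", "ifcm", "km", "fcm"),
                        template = NULL, mFuzz = 2, tol = 1e-5,
                        maxIter = 100L, entropyBins = 256L,
                        seed = NULL) {
  mode <- match.arg(mode)
  cellImg <- img[cell$r0:cell$r1, cell$c0:cell$c1, drop = FALSE]
  intens <- as.vector(cellImg)
  n <- length(intens)

  if (mode %in% c("ikm", "ifcm")) {
    if (is.null(template))
      msgStop("microseg_parameter_error",
              "improved modes need a Gaussian template")
    fm <- pixelFeatures(img, cell, template, entropyBins = entropyBins)
    red <- pcaReduce(fm)
    init <- initCenters(fm, red, kBg, cell)
    fit <- if (mode == "ikm")
      kmeansTwoClass(red$Z, init, tol = tol, maxIter = maxIter)
    else
      fcmTwoClass(red$Z, init, mFuzz = mFuzz, tol = tol,
                  maxIter = maxIter)
  } else {
    X <- matrix(intens, ncol = 1L)
    pick <- withSeed(seed, sample.int(n, 2L))
    init <- X[pick, , drop = FALSE]
    fit <- if (mode == "km")
      kmeansTwoClass(X, init, tol = tol, maxIter = maxIter)
    else
      fcmTwoClass(X, init, mFuzz = mFuzz, tol = tol, maxIter = maxIter)
  }
  fit@mode <- mode

  lab <- fit@labels
  n1 <- sum(lab == 1L); n2 <- sum(lab == 2L)
  m1 <- if (n1) mean(intens[lab == 1L]) else NA_real_
  m2 <- if (n2) mean(intens[lab == 2L]) else NA_real_
  # the foreground cluster is the strictly brighter one; with equal
  # means there is no intensity evidence of a spot (degenerate
  # background-only cells), and an empty background cluster marks the
  # saturated all-foreground failure mode for the refinement step
  fgCluster <- if (n2 == 0L) 0L
  else if (n1 == 0L) 2L
  else if (m2 > m1) 2L
  else if (m1 > m2) 1L
  else 0L
  mask <- matrix(lab == fgCluster & fgCluster > 0L,
                 nrow(cellImg), ncol(cellImg))
  list(mask = mask, fit = fit)
}
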