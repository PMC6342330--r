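# Shared fixtures and independent oracles.

# Disc mask with the generator's convention: pixel centers within
# `diam/2` of the exact cell center.
discMask <- function(n, diam, ctr = (n + 1) / 2) {
  ii <- matrix(seq_len(n), n, n)
  jj <- t(ii)
  sqrt((ii - ctr)^2 + (jj - ctr)^2) <= diam / 2
}

# A single noise-free spot cell (disc of `fg` on constant `bg`).
discCellImage <- function(n = 20, diam = 12, fg = 10000, bg = 500) {
  img <- matrix(bg, n, n)
  img[discMask(n, diam)] <- fg
  img
}

cellSpec <- function(r0, r1, c0, c1) {
  list(r0 = r0, r1 = r1, c0 = c0, c1 = c1,
       rc = floor((r0 + r1) / 2), cc = floor((c0 + c1) / 2),
       row = 1L, col = 1L)
}

# Independent replicate-pad + sliding-window oracle (loop-based, no
# shared code with the implementation).
oraclePad <- function(m, k) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0, nr + 2 * k, nc + 2 * k)
  for (i in seq_len(nr + 2 * k)) {
    for (j in seq_len(nc + 2 * k)) {
      out[i, j] <- m[min(max(i - k, 1), nr), min(max(j - k, 1), nc)]
    }
  }
  out
}

oracleMedianFilter <- function(m, size) {
  k <- (size - 1) %/% 2
  p <- oraclePad(m, k)
  out <- m
  for (i in seq_len(nrow(m)))
    for (j in seq_len(ncol(m)))
      out[i, j] <- median(p[i:(i + 2 * k), j:(j + 2 * k)])
  out
}

# Naive iterative geodesic reconstruction-by-dilation (unit structuring
# element), the literal definition.
oracleReconstruct <- function(signal, drop) {
  marker <- signal - drop * diff(range(signal))
  repeat {
    old <- marker
    dil <- pmax(marker,
                c(marker[1], marker[-length(marker)]),
                c(marker[-1], marker[length(marker)]))
    marker <- pmin(dil, signal)
    if (identical(marker, old)) return(marker)
  }
}

# Exhaustive between-class-variance sweep (independent of the
# implementation's vectorized form).
oracleOtsu <- function(x) {
  vals <- sort(unique(x))
  best <- -Inf; bestT <- NA
  for (t in vals[-1]) {
    lo <- x[x < t]; hi <- x[x >= t]
    crit <- (length(lo) / length(x)) * (length(hi) / length(x)) *
      (mean(lo) - mean(hi))^2
    if (crit > best + 1e-12) { best <- crit; bestT <- t }
  }
  bestT
}

# Literal Eq 1 / Eq 2 fixed-point iterator, loop-coded.
oracleFcm <- function(X, init, m = 2, tol = 1e-10, maxIter = 500) {
  X <- as.matrix(X)
  centers <- as.matrix(init)
  n <- nrow(X)
  for (it in seq_len(maxIter)) {
    U <- matrix(0, n, 2)
    for (j in seq_len(n)) {
      d <- c(sqrt(sum((X[j, ] - centers[1, ])^2)),
             sqrt(sum((X[j, ] - centers[2, ])^2)))
      if (any(d == 0)) {
        U[j, which(d == 0)[1]] <- 1
      } else {
        for (i in 1:2)
          U[j, i] <- 1 / sum((d[i] / d)^(2 / (m - 1)))
      }
    }
    newC <- centers
    for (i in 1:2) {
      w <- U[, i]^m
      newC[i, ] <- colSums(w * X) / sum(w)
    }
    delta <- max(abs(newC - centers))
    centers <- newC
    if (delta < tol) break
  }
  list(centers = centers, U = U)
}

# One Lloyd assignment/update pass, loop-coded, for fixed-point checks.
oracleNearest <- function(X, centers) {
  apply(X, 1, function(x) {
    d <- c(sum((x - centers[1, ])^2), sum((x - centers[2, ])^2))
    if (d[1] <= d[2]) 1L else 2L
  })
}
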