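# Shared low-level helpers: structured errors, matrix padding, window
# stacks, and the median-of-9 sorting network used by the denoiser.

#' @noRd
msgStop <- function(class, fmt, ...) {
  cond <- structure(
    list(message = sprintf(fmt, ...), call = sys.call(-1)),
    class = c(class, "microsegError", "error", "condition")
  )
  stop(cond)
}

#' @noRd
assertMatrixImage <- function(img, arg = "img") {
  if (!is.matrix(img) || !is.numeric(img) || length(img) == 0L)
    msgStop("microseg_parameter_error",
            "'%s' must be a non-empty numeric matrix", arg)
  if (any(img < 0))
    msgStop("microseg_parameter_error",
            "'%s' must be non-negative (intensity raster)", arg)
  invisible(TRUE)
}

# Replicate-pad a matrix by `k` pixels on every side.
#' @noRd
padReplicate <- function(m, k) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- c(rep(1L, k), seq_len(nr), rep(nr, k))
  ci <- c(rep(1L, k), seq_len(nc), rep(nc, k))
  m[ri, ci, drop = FALSE]
}

# Stack of sliding-window values: one row per pixel (column-major pixel
# order), one column per window offset, offsets ordered column-major so
# that a row matches as.vector() of the corresponding window.
#' @noRd
windowStack <- function(m, half) {
  p <- padReplicate(m, half)
  nr <- nrow(m); nc <- ncol(m)
  w <- 2L * half + 1L
  out <- matrix(0, nrow = nr * nc, ncol = w * w)
  idx <- 1L
  for (dj in -half:half) {
    for (di in -half:half) {
      out[, idx] <- as.vector(p[(half + 1L + di):(half + nr + di),
                                (half + 1L + dj):(half + nc + dj),
                                drop = FALSE])
      idx <- idx + 1L
    }
  }
  out
}

# Row-wise median of a 9-column matrix via the classic 19-exchange
# min/max network (exact median, vectorized over rows).
#' @noRd
rowMedian9 <- function(A) {
  swp <- function(a, b) {
    lo <- pmin(A[, a], A[, b])
    A[, b] <<- pmax(A[, a], A[, b])
    A[, a] <<- lo
  }
  swp(2L, 3L); swp(5L, 6L); swp(8L, 9L)
  swp(1L, 2L); swp(4L, 5L); swp(7L, 8L)
  swp(2L, 3L); swp(5L, 6L); swp(8L, 9L)
  swp(1L, 4L); swp(6L, 9L); swp(5L, 8L)
  swp(4L, 7L); swp(2L, 5L); swp(3L, 6L)
  swp(5L, 8L); swp(5L, 3L); swp(7L, 5L)
  swp(5L, 3L)
  A[, 5L]
}

# Seeded evaluation that does not disturb the caller's RNG state.
#' @noRd
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  withr::with_seed(as.integer(seed), expr)
}

# Runs of TRUE values in a logical vector -> data.frame(start, end).
#' @noRd
logicalRuns <- function(x) {
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(start = starts[r$values], end = ends[r$values])
}

#' @noRd
fmtNum <- function(x, digits = 6) formatC(x, digits = digits, format = "g")
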