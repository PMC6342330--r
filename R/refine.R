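# Adaptive adjustment of segmented cell masks: foreground pixels outside
# a circle of diameter s (the rough spot size from gridding) are noise
# and removed, and implausible cells are flagged as missing spots. The
# missing rule uses the printed constants: a spot is missing when fewer
# than half of 3.14*s foreground pixels lie inside the circle, or when
# the circle is well filled but more than 90% of the whole rectangular
# cell is foreground (the saturated false-segmentation case). Counts
# n_f are taken before noise removal so the saturation branch can fire.

#' Remove foreground pixels outside the spot circle
#'
#' @param mask logical (or 0/1) cell mask.
#' @param center numeric `c(i, j)` circle center in the mask's own
#'   coordinates.
#' @param s circle diameter in pixels; pixels at distance exactly `s/2`
#'   count as inside.
#' @return logical mask with outside-circle pixels cleared.
#' @examples
#' m <- matrix(TRUE, 5, 5)
#' sum(removeOutsideCircle(m, c(3, 3), 4))
#' @export
removeOutsideCircle <- function(mask, center, s) {
  if (!(is.numeric(s) && length(s) == 1L && s > 0))
    msgStop("microseg_parameter_error", "circle diameter s must be > 0")
  nr <- nrow(mask); nc <- ncol(mask)
  ii <- matrix(seq_len(nr), nr, nc)
  jj <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  inside <- sqrt((ii - center[1L])^2 + (jj - center[2L])^2) <= s / 2
  out <- (mask > 0) & inside
  out
}

#' Missing-spot rule
#'
#' A spot is missing when `n_c < 0.5 * (3.14 * s)` — too few recognized
#' foreground pixels inside the circle — or when `n_c >= 3.14 * s` and
#' `n_f > 0.9 * n_s` — a circle-filling segmentation that also covers
#' nearly the whole rectangular cell, i.e. a false, saturated result.
#' Constants exactly as printed; `rule = "area"` replaces the linear
#' `3.14 * s` term by the circle area `3.14 * (s/2)^2` (see the
#' vignette).
#'
#' @param nS total pixels of the cell.
#' @param nF foreground pixels in the cell (before noise removal).
#' @param nC foreground pixels inside the circle.
#' @param s circle diameter (pixels).
#' @param rule `"linear"` (printed form, default) or `"area"`.
#' @return logical: is the spot missing?
#' @examples
#' flagMissing(400, 400, 16, 10)   # saturated cell -> TRUE
#' @export
flagMissing <- function(nS, nF, nC, s, rule = c("linear", "area")) {
  rule <- match.arg(rule)
  if (!(nC <= nF && nF <= nS && nC >= 0))
    msgStop("microseg_parameter_error",
            "inconsistent counts: need 0 <= nC <= nF <= nS")
  ref <- if (rule == "linear") 3.14 * s else 3.14 * (s / 2)^2
  (nC < 0.5 * ref) || (nC >= ref && nF > 0.9 * nS)
}

#' Refine all cell masks of a sub-grid
#'
#' Applies the circle-noise removal and the missing-spot rule to every
#' cell: counts total (`nS`), foreground before removal (`nFBefore`) and
#' inside-circle (`nC`) pixels, clears outside-circle noise, and replaces
#' the mask of any flagged cell by all-background.
#'
#' @param masks list of logical cell masks, one per row of
#'   `gridCells(grid)` (same order).
#' @param grid a [SpotGrid-class]; supplies `s` and the cell geometry.
#' @param rule missing rule, see [flagMissing()].
#' @param circleCenter `"centroid"` (default) centers each cell's circle
#'   on the centroid of its recognized foreground, which keeps the
#'   circle concentric with the actual spot under small gridding jitter;
#'   `"cell"` uses the cell's geometric center.
#' @return list with `masks` (refined), `report` (per-spot
#'   `data.frame`: `row`, `col`, `nS`, `nFBefore`, `nF`, `nC`,
#'   `removed`, `isMissing`) and `s`.
#' @export
refineSubgrid <- function(masks, grid, rule = c("linear", "area"),
                          circleCenter = c("centroid", "cell")) {
  rule <- match.arg(rule)
  circleCenter <- match.arg(circleCenter)
  cells <- gridCells(grid)
  if (length(masks) != nrow(cells))
    msgStop("microseg_parameter_error",
            "need one mask per grid cell (%d masks, %d cells)",
            length(masks), nrow(cells))
  s <- spotSize(grid)
  rep <- vector("list", length(masks))
  out <- vector("list", length(masks))
  for (idx in seq_along(masks)) {
    cell <- cells[idx, ]
    m <- masks[[idx]]
    nS <- length(m)
    nFBefore <- sum(m)
    # exact geometric center (possibly half-integer), not the rounded
    # center pixel, so the circle stays concentric with the cell
    ctr <- c((cell$r1 - cell$r0) / 2 + 1, (cell$c1 - cell$c0) / 2 + 1)
    if (circleCenter == "centroid" && nFBefore > 0L) {
      fgIdx <- which(m > 0, arr.ind = TRUE)
      ctr <- c(mean(fgIdx[, 1L]), mean(fgIdx[, 2L]))
    }
    cleaned <- removeOutsideCircle(m, ctr, s)
    nC <- sum(cleaned)
    miss <- flagMissing(nS, nFBefore, nC, s, rule = rule)
    if (miss) cleaned <- matrix(FALSE, nrow(m), ncol(m))
    out[[idx]] <- cleaned
    rep[[idx]] <- data.frame(
      row = cell$row, col = cell$col, nS = nS, nFBefore = nFBefore,
      nF = sum(cleaned), nC = nC, removed = nFBefore - nC,
      isMissing = miss)
  }
  list(masks = out, report = do.call(rbind, rep), s = s)
}
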