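# Gridding: locate the horizontal/vertical lines separating spot cells
# via projection profiles, morphological-reconstruction filtering of the
# profile, and a maximum between-class-variance (Otsu) threshold on the
# filtered signal. Sub-threshold runs are inter-spot gaps; interior gap
# midpoints become grid lines and the threshold crossings around each
# spot band become boundary-line pairs.

#' Projection profile of an intensity raster
#'
#' @param img numeric intensity matrix.
#' @param axis `"rows"` sums each row (profile along the vertical axis,
#'   length `nrow(img)`), `"cols"` sums each column.
#' @return numeric vector of intensity sums.
#' @examples
#' projectionProfile(matrix(1, 2, 3), "rows")
#' @export
projectionProfile <- function(img, axis = c("rows", "cols")) {
  assertMatrixImage(img)
  axis <- match.arg(axis)
  if (axis == "rows") rowSums(img) else colSums(img)
}

#' Morphological reconstruction filter for a 1-D signal
#'
#' Grayscale reconstruction-by-dilation of `signal - markerDrop * range`
#' under `signal`: geodesic dilation of the dropped marker, clipped by the
#' signal, iterated to stability. Peaks shorter than the drop are
#' flattened while taller structures survive with their upper part
#' intact; the output never exceeds the input.
#'
#' @param signal numeric vector, length `>= 3`.
#' @param markerDrop drop as a fraction of the signal range, in (0, 1).
#' @return filtered signal, same length.
#' @examples
#' reconstructFilter(c(0, 5, 0, 1, 0), markerDrop = 0.5)
#' @export
reconstructFilter <- function(signal, markerDrop = 0.3) {
  if (length(signal) < 3L)
    msgStop("microseg_parameter_error", "signal must have length >= 3")
  if (!(markerDrop > 0 && markerDrop < 1))
    msgStop("microseg_parameter_error",
            "markerDrop must lie in (0, 1), got %s", fmtNum(markerDrop))
  rng <- diff(range(signal))
  marker <- signal - markerDrop * rng
  n <- length(signal)
  # alternating forward/backward raster sweeps of the geodesic dilation
  for (pass in seq_len(2L * n)) {
    old <- marker
    for (i in 2:n)
      marker[i] <- min(signal[i], max(marker[i], marker[i - 1L]))
    for (i in (n - 1L):1L)
      marker[i] <- min(signal[i], max(marker[i], marker[i + 1L]))
    if (identical(marker, old)) break
  }
  marker
}

#' Maximum between-class-variance threshold of a 1-D signal
#'
#' Sweeps every distinct signal value as a candidate threshold `t`,
#' splitting samples into `x < t` and `x >= t`, and returns the `t`
#' maximizing the between-class variance `w0 * w1 * (mu0 - mu1)^2`
#' (Otsu's criterion applied to the signal values); ties break toward the
#' lower threshold.
#'
#' @param signal numeric vector with at least two distinct values.
#' @return the scalar threshold.
#' @examples
#' betweenClassThreshold(c(0, 0, 0, 10, 10, 10))
#' @export
betweenClassThreshold <- function(signal) {
  vals <- sort(unique(signal))
  if (length(vals) < 2L)
    msgStop("microseg_degenerate_threshold",
            "constant signal: between-class threshold is undefined")
  cand <- vals[-1L]
  n <- length(signal)
  crit <- vapply(cand, function(t) {
    lo <- signal < t
    w0 <- mean(lo)
    w0 * (1 - w0) * (mean(signal[lo]) - mean(signal[!lo]))^2
  }, numeric(1))
  cand[which.max(crit)]  # which.max returns the first (lowest) maximizer
}

#' Grid lines and boundary lines from a thresholded profile
#'
#' Runs of sub-threshold samples (`x < thresh`) are inter-spot gaps; each
#' interior gap contributes its midpoint as a grid line. Runs at or above
#' the threshold are spot bands; each band contributes a boundary-line
#' pair (half-integer coordinates at the pixel borders), so
#' leading/trailing gaps mark the outer boundary lines at their inner
#' edges.
#'
#' Because the between-class threshold sits well inside a spot band's
#' profile, its direct crossings clip the faint outermost band samples
#' (a disc's outer rows have short chords) and the boundary pair would
#' under-measure the spot. With `bandFrac > 0` each gap run is therefore
#' trimmed back to its background envelope before lines are placed: end
#' samples exceeding `min(run) + bandFrac * (thresh - min(run))` are
#' reassigned to the adjacent band. `bandFrac = 0` keeps the raw
#' threshold crossings.
#'
#' @param filtered numeric signal (typically a reconstruction-filtered
#'   projection profile).
#' @param thresh threshold value.
#' @param bandFrac gap-trim fraction in `[0, 1)` (default 0.25).
#' @return list with `lines` (interior grid-line coordinates) and
#'   `bounds` (boundary-line coordinates, two per band).
#' @examples
#' p <- c(0, 0, 9, 9, 0, 0, 0, 9, 9, 0)
#' extractGridLines(p, 5)
#' @export
extractGridLines <- function(filtered, thresh, bandFrac = 0.25) {
  if (bandFrac < 0 || bandFrac >= 1)
    msgStop("microseg_parameter_error",
            "bandFrac must lie in [0, 1), got %s", fmtNum(bandFrac))
  below <- filtered < thresh
  if (!any(below))
    msgStop("microseg_no_gap",
            "no sub-threshold samples: cannot place grid lines")
  if (all(below))
    msgStop("microseg_no_gap",
            "no spot bands: every sample is sub-threshold")
  n <- length(filtered)
  if (bandFrac > 0) {
    runs <- logicalRuns(below)
    for (g in seq_len(nrow(runs))) {
      a <- runs$start[g]; b <- runs$end[g]
      t2 <- min(filtered[a:b]) + bandFrac * (thresh - min(filtered[a:b]))
      while (a <= b && filtered[a] > t2) { below[a] <- FALSE; a <- a + 1L }
      while (b >= a && filtered[b] > t2) { below[b] <- FALSE; b <- b - 1L }
    }
    if (!any(below))
      msgStop("microseg_no_gap",
              "no sub-threshold samples left after gap trimming")
  }
  gaps <- logicalRuns(below)
  bands <- logicalRuns(!below)
  interior <- gaps$start > 1L & gaps$end < n
  list(
    lines = (gaps$start[interior] + gaps$end[interior]) / 2,
    bounds = sort(c(bands$start - 0.5, bands$end + 0.5))
  )
}

#' Revise grid lines toward quasi-uniform pitch
#'
#' Heuristic repair of the extracted lines: lines closer than
#' `mergeFactor` times the median pitch are merged to their midpoint, and
#' gaps wider than `insertFactor` times the median pitch get evenly
#' spaced lines restored (as many as the gap holds at median pitch).
#'
#' @param lines numeric grid-line coordinates.
#' @param insertFactor gap width, in median pitches, above which lines
#'   are inserted (default 1.5).
#' @param mergeFactor spacing, in median pitches, below which adjacent
#'   lines merge (default 0.5).
#' @return revised, sorted line coordinates.
#' @examples
#' reviseGrid(c(10, 30, 70))   # 50 restored
#' @export
reviseGrid <- function(lines, insertFactor = 1.5, mergeFactor = 0.5) {
  lines <- sort(lines)
  if (length(lines) < 2L) {
    warning("fewer than 2 grid lines: revision skipped")
    return(lines)
  }
  med <- median(diff(lines))
  # merge near-duplicates (closest pair first)
  repeat {
    d <- diff(lines)
    if (!length(d) || min(d) >= mergeFactor * med) break
    i <- which.min(d)
    lines <- c(lines[seq_len(i - 1L)],
               (lines[i] + lines[i + 1L]) / 2,
               lines[-seq_len(i + 1L)])
  }
  # insert lines into oversized gaps
  med <- median(diff(lines))
  out <- lines[1L]
  for (i in seq_len(length(lines) - 1L)) {
    g <- lines[i + 1L] - lines[i]
    if (g > insertFactor * med) {
      k <- round(g / med)
      out <- c(out, lines[i] + seq_len(k - 1L) * g / k)
    }
    out <- c(out, lines[i + 1L])
  }
  out
}

# One axis of the gridding chain.
#' @noRd
gridAxis <- function(img, axis, markerDrop, bandFrac = 0.25) {
  prof <- projectionProfile(img, axis)
  filt <- reconstructFilter(prof, markerDrop)
  th <- betweenClassThreshold(filt)
  gl <- extractGridLines(filt, th, bandFrac = bandFrac)
  lines <- if (length(gl$lines) >= 2L) reviseGrid(gl$lines) else gl$lines
  bounds <- gl$bounds
  nBands <- length(bounds) / 2
  pitch <- if (length(lines) >= 2L) mean(diff(lines))
  else (bounds[length(bounds)] - bounds[1L]) / nBands
  widths <- bounds[seq(2L, length(bounds), 2L)] -
    bounds[seq(1L, length(bounds), 2L)]
  list(lines = lines, bounds = bounds, pitch = pitch,
       meanWidth = mean(widths))
}

#' Grid a sub-grid image into spot cells
#'
#' Runs the full gridding chain (projection profile, reconstruction
#' filter, between-class threshold, line extraction, heuristic revision)
#' on both axes, estimates the spot diameter `d` as the mean grid pitch
#' of the two axes and the rough spot size `s` from the boundary-pair
#' widths, and tiles the region between the outer boundary lines into
#' spot cells delimited by consecutive grid lines.
#'
#' @param img numeric intensity raster (preprocessed; when two channels
#'   are available their sum is the usual input).
#' @param markerDrop reconstruction marker drop (fraction of profile
#'   range). The default 0.1 flattens profile noise while preserving
#'   weak spot bands; drops much larger than the prominence of the
#'   weakest band (e.g. a column with several missing spots) can push
#'   it below the between-class threshold and lose a whole grid line.
#' @param sFormula `"mean"` (default) averages the two per-axis mean
#'   boundary widths; `"sum"` adds them (the literal reading of the
#'   printed formula; see the vignette).
#' @param bandFrac gap-trim fraction for boundary placement, see
#'   [extractGridLines()].
#' @return a [SpotGrid-class] object.
#' @seealso [projectionProfile()], [reviseGrid()]
#' @export
gridImage <- function(img, markerDrop = 0.1,
                      sFormula = c("mean", "sum"), bandFrac = 0.25) {
  assertMatrixImage(img)
  sFormula <- match.arg(sFormula)
  hh <- gridAxis(img, "rows", markerDrop, bandFrac)
  vv <- gridAxis(img, "cols", markerDrop, bandFrac)
  d <- (hh$pitch + vv$pitch) / 2
  s <- if (sFormula == "mean") (hh$meanWidth + vv$meanWidth) / 2
  else hh$meanWidth + vv$meanWidth

  # cells tile the whole sub-grid: outer edges one pitch beyond the
  # outermost interior lines (clipped to the image), so border cells are
  # centered on their spots like interior ones
  outerEdges <- function(lines, bounds, pitch, extent) {
    if (length(lines) >= 1L)
      c(max(0.5, lines[1L] - pitch),
        min(extent + 0.5, lines[length(lines)] + pitch))
    else {
      pad <- max(0, (pitch - (bounds[2L] - bounds[1L])) / 2)
      c(max(0.5, bounds[1L] - pad),
        min(extent + 0.5, bounds[2L] + pad))
    }
  }
  ro <- outerEdges(hh$lines, hh$bounds, hh$pitch, nrow(img))
  co <- outerEdges(vv$lines, vv$bounds, vv$pitch, ncol(img))
  rEdges <- c(ro[1L], hh$lines, ro[2L])
  cEdges <- c(co[1L], vv$lines, co[2L])
  if (is.unsorted(rEdges, strictly = TRUE) ||
      is.unsorted(cEdges, strictly = TRUE))
    msgStop("microseg_gridding_error",
            "grid lines and boundary lines are not consistently ordered")
  nR <- length(rEdges) - 1L
  nC <- length(cEdges) - 1L
  cells <- expand.grid(row = seq_len(nR), col = seq_len(nC))
  cells <- cells[order(cells$row, cells$col), , drop = FALSE]
  cells$r0 <- floor(rEdges[cells$row]) + 1L
  cells$r1 <- floor(rEdges[cells$row + 1L])
  cells$c0 <- floor(cEdges[cells$col]) + 1L
  cells$c1 <- floor(cEdges[cells$col + 1L])
  cells$rc <- floor((cells$r0 + cells$r1) / 2)
  cells$cc <- floor((cells$c0 + cells$c1) / 2)
  rownames(cells) <- NULL

  new("SpotGrid",
      hLines = hh$lines, vLines = vv$lines,
      hBounds = hh$bounds, vBounds = vv$bounds,
      d = d, s = s, cells = cells)
}
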