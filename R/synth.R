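# Synthetic two-channel microarray sub-grid generator with pixel-level
# ground truth. Spots sit on a regular grid (one per cell), take one of
# four shapes (or are missing), and carry a per-spot true log2 expression
# ratio defined from the generated pre-noise foreground excess over
# background — so the truth is independent of the pipeline's own
# extraction. Noise is additive Gaussian per channel, clipped to the
# 16-bit range.

SHAPE_NAMES <- c("circle", "donut", "comet", "irregular", "missing")

#' Construct synthetic sub-grid generator parameters
#'
#' @param nRows,nCols spot rows / columns.
#' @param cellPx cell pitch in pixels.
#' @param spotDiameterPx nominal spot diameter in pixels
#'   (`0 < spotDiameterPx < cellPx`).
#' @param shapeMix named proportions over
#'   `c("circle","donut","comet","irregular","missing")`; must sum to 1.
#' @param fgLevel mean foreground intensity per channel; length 1
#'   (recycled) or 2 (`cy3`, `cy5`), in 16-bit counts.
#' @param bgLevel mean background intensity (counts).
#' @param noiseSigma additive Gaussian noise sd (counts).
#' @param mSd sd of the per-spot true log2-ratio draw; 0 gives every spot
#'   the ratio implied by `fgLevel`.
#' @param qualityPreset label recorded on the object.
#' @param seed integer RNG seed.
#' @return a validated [SynthParams-class] object.
#' @examples
#' p <- synthParams(nRows = 4, nCols = 4, noiseSigma = 0)
#' sg <- generateSubgrid(p)
#' sum(truthMask(sg))
#' @export
synthParams <- function(nRows = 10L, nCols = 10L, cellPx = 20L,
                        spotDiameterPx = 12,
                        shapeMix = c(circle = 1, donut = 0, comet = 0,
                                     irregular = 0, missing = 0),
                        fgLevel = c(cy3 = 10000, cy5 = 10000),
                        bgLevel = 500, noiseSigma = 100, mSd = 0,
                        qualityPreset = "custom", seed = 1L) {
  if (length(fgLevel) == 1L) fgLevel <- c(cy3 = fgLevel, cy5 = fgLevel)
  names(fgLevel) <- c("cy3", "cy5")
  if (is.null(names(shapeMix)) ||
      !all(names(shapeMix) %in% SHAPE_NAMES))
    msgStop("microseg_parameter_error",
            "shapeMix must be named over {%s}",
            paste(SHAPE_NAMES, collapse = ", "))
  mix <- setNames(numeric(5), SHAPE_NAMES)
  mix[names(shapeMix)] <- shapeMix
  if (abs(sum(mix) - 1) > 1e-8)
    msgStop("microseg_parameter_error",
            "shapeMix proportions must sum to 1 (got %s)", fmtNum(sum(mix)))
  obj <- new("SynthParams",
             nRows = as.integer(nRows), nCols = as.integer(nCols),
             cellPx = as.integer(cellPx),
             spotDiameterPx = as.numeric(spotDiameterPx),
             shapeMix = mix,
             fgLevel = setNames(as.numeric(fgLevel), c("cy3", "cy5")),
             bgLevel = as.numeric(bgLevel),
             noiseSigma = as.numeric(noiseSigma), mSd = as.numeric(mSd),
             qualityPreset = qualityPreset, seed = as.integer(seed))
  validObject(obj)
  obj
}

#' Quality presets for the synthetic generator
#'
#' Three fixed parameter bundles emulating good, normal and poor scan
#' quality: "good" has high foreground/background contrast (ratio 20) and
#' low noise (1% of the foreground level), "poor" has low contrast
#' (ratio 1.4), heavy noise, and more irregular/missing spots; "normal"
#' sits strictly between the two on both axes.
#'
#' @param name one of `"good"`, `"normal"`, `"poor"`.
#' @param nRows,nCols spot layout (default 10 x 10).
#' @param seed integer RNG seed.
#' @return a [SynthParams-class] object.
#' @examples
#' qualityPreset("poor", seed = 7)
#' @export
qualityPreset <- function(name = c("good", "normal", "poor"),
                          nRows = 10L, nCols = 10L, seed = 1L) {
  if (length(name) != 1L || !name %in% c("good", "normal", "poor"))
    msgStop("microseg_parameter_error",
            "unknown quality preset '%s'", paste(name, collapse = ","))
  args <- switch(name,
    good = list(fgLevel = 10000, bgLevel = 500, noiseSigma = 100,
                shapeMix = c(circle = 0.90, donut = 0.04, comet = 0.02,
                             irregular = 0.02, missing = 0.02)),
    normal = list(fgLevel = 4000, bgLevel = 800, noiseSigma = 150,
                  shapeMix = c(circle = 0.70, donut = 0.10, comet = 0.07,
                               irregular = 0.08, missing = 0.05)),
    poor = list(fgLevel = 1400, bgLevel = 1000, noiseSigma = 200,
                shapeMix = c(circle = 0.50, donut = 0.15, comet = 0.10,
                             irregular = 0.15, missing = 0.10))
  )
  do.call(synthParams, c(args, list(
    nRows = nRows, nCols = nCols, mSd = 0.4,
    qualityPreset = name, seed = seed)))
}

# Pixel set of one spot shape in cell-local coordinates. Returns a list
# with `mask` (logical cellPx x cellPx) and `tail` (numeric matrix of
# off-spot excess fractions, comet only). Consumes RNG for the random
# shape parameters.
#' @noRd
spotShape <- function(shape, cellPx, r0) {
  ctr <- (cellPx + 1) / 2
  ii <- matrix(seq_len(cellPx), cellPx, cellPx)
  jj <- t(ii)
  dist <- sqrt((ii - ctr)^2 + (jj - ctr)^2)
  tailM <- NULL
  mask <- switch(shape,
    circle = dist <= r0,
    donut = dist <= r0 & dist > 0.45 * r0,
    comet = {
      ang <- runif(1, 0, 2 * pi)
      len <- 0.6 * r0
      theta <- atan2(jj - ctr, ii - ctr)
      dAng <- abs(((theta - ang + pi) %% (2 * pi)) - pi)
      inTail <- dist > r0 & dist <= r0 + len & dAng < pi / 6
      tailM <- matrix(0, cellPx, cellPx)
      tailM[inTail] <- 1 - (dist[inTail] - r0) / len
      dist <= r0
    },
    irregular = {
      ctrl <- runif(8, 0.75, 1.25) * r0
      thetaGrid <- seq(0, 2 * pi, length.out = 9L)
      theta <- atan2(jj - ctr, ii - ctr) %% (2 * pi)
      rTheta <- approx(thetaGrid, c(ctrl, ctrl[1]), xout = theta)$y
      dist <= matrix(rTheta, cellPx, cellPx)
    },
    missing = matrix(FALSE, cellPx, cellPx)
  )
  list(mask = mask, tail = tailM)
}

#' Generate a synthetic two-channel sub-grid with ground truth
#'
#' Lays out `nRows x nCols` spot cells, draws one shape per spot from
#' `shapeMix`, assigns each non-missing spot a true log2 ratio
#' `trueM` (drawn `N(0, mSd)` plus the channel-level offset implied by
#' `fgLevel`), renders both channels as background plus per-spot
#' foreground excess, and finally adds clipped Gaussian noise. The truth
#' mask marks exactly the constant-excess spot pixels (comet tails decay
#' off-spot and are treated as bright contamination, not spot). Output is
#' bit-reproducible for a fixed parameter object.
#'
#' @param params a [SynthParams-class] object.
#' @return a [MicroarraySubgrid-class].
#' @examples
#' sg <- generateSubgrid(synthParams(nRows = 3, nCols = 3, noiseSigma = 0))
#' truthTable(sg)[1:3, ]
#' @export
generateSubgrid <- function(params) {
  stopifnot(is(params, "SynthParams"))
  validObject(params)
  nR <- params@nRows; nC <- params@nCols; cp <- params@cellPx
  H <- nR * cp; W <- nC * cp
  r0 <- params@spotDiameterPx / 2
  e3base <- params@fgLevel[["cy3"]] - params@bgLevel
  e5base <- params@fgLevel[["cy5"]] - params@bgLevel

  withSeed(params@seed, {
    mask <- matrix(0L, H, W)
    ex3 <- matrix(0, H, W)
    ex5 <- matrix(0, H, W)
    tab <- vector("list", nR * nC)
    idx <- 1L
    for (r in seq_len(nR)) {
      for (cc in seq_len(nC)) {
        shape <- sample(SHAPE_NAMES, 1L, prob = params@shapeMix)
        rows <- ((r - 1L) * cp + 1L):(r * cp)
        cols <- ((cc - 1L) * cp + 1L):(cc * cp)
        if (shape == "missing") {
          tab[[idx]] <- data.frame(row = r, col = cc, shape = shape,
                                   trueM = NA_real_, isMissing = TRUE)
        } else {
          mDraw <- if (params@mSd > 0) rnorm(1L, 0, params@mSd) else 0
          e3 <- e3base * 2^(mDraw / 2)
          e5 <- e5base * 2^(-mDraw / 2)
          sh <- spotShape(shape, cp, r0)
          mask[rows, cols][sh$mask] <- 1L
          ex3[rows, cols][sh$mask] <- e3
          ex5[rows, cols][sh$mask] <- e5
          if (!is.null(sh$tail)) {
            ex3[rows, cols] <- ex3[rows, cols] + e3 * sh$tail
            ex5[rows, cols] <- ex5[rows, cols] + e5 * sh$tail
          }
          tab[[idx]] <- data.frame(row = r, col = cc, shape = shape,
                                   trueM = log2(e3 / e5),
                                   isMissing = FALSE)
        }
        idx <- idx + 1L
      }
    }
    cy3 <- params@bgLevel + ex3
    cy5 <- params@bgLevel + ex5
    if (params@noiseSigma > 0) {
      cy3 <- cy3 + rnorm(H * W, 0, params@noiseSigma)
      cy5 <- cy5 + rnorm(H * W, 0, params@noiseSigma)
    }
    cy3 <- matrix(pmin(pmax(cy3, 0), 65535), H, W)
    cy5 <- matrix(pmin(pmax(cy5, 0), 65535), H, W)

    new("MicroarraySubgrid",
        cy3 = cy3, cy5 = cy5, mask = mask,
        expression = do.call(rbind, tab),
        hLines = if (nR > 1L) seq_len(nR - 1L) * cp + 0.5 else numeric(),
        vLines = if (nC > 1L) seq_len(nC - 1L) * cp + 0.5 else numeric(),
        params = params)
  })
}

#' Write a synthetic sub-grid bundle to disk
#'
#' Writes `cy3.tif` / `cy5.tif` (16-bit grayscale), `mask.png` (8-bit,
#' 0/255), `expression.csv`, `gridlines.csv` and a `params.json` sidecar.
#'
#' @param x a [MicroarraySubgrid-class].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
writeSubgrid <- function(x, dir) {
  stopifnot(is(x, "MicroarraySubgrid"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tiff::writeTIFF(x@cy3 / 65535, file.path(dir, "cy3.tif"),
                  bits.per.sample = 16L)
  tiff::writeTIFF(x@cy5 / 65535, file.path(dir, "cy5.tif"),
                  bits.per.sample = 16L)
  png::writePNG(x@mask + 0, file.path(dir, "mask.png"))
  write.csv(x@expression, file.path(dir, "expression.csv"),
            row.names = FALSE)
  gl <- rbind(
    data.frame(axis = "H", coordinate = x@hLines),
    data.frame(axis = "V", coordinate = x@vLines))
  write.csv(gl, file.path(dir, "gridlines.csv"), row.names = FALSE)
  p <- x@params
  jsonlite::write_json(list(
    nRows = p@nRows, nCols = p@nCols, cellPx = p@cellPx,
    spotDiameterPx = p@spotDiameterPx, shapeMix = as.list(p@shapeMix),
    fgLevel = as.list(p@fgLevel), bgLevel = p@bgLevel,
    noiseSigma = p@noiseSigma, mSd = p@mSd,
    qualityPreset = p@qualityPreset, seed = p@seed),
    file.path(dir, "params.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a 16-bit grayscale channel image (TIFF or PNG)
#'
#' @param path file path.
#' @return numeric intensity matrix on the native 16-bit count scale.
#' @export
readChannelImage <- function(path) {
  if (!file.exists(path))
    msgStop("microseg_io_error", "input image '%s' not found", path)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    tif = , tiff = tiff::readTIFF(path),
    png = png::readPNG(path),
    msgStop("microseg_io_error", "unsupported image format '%s'", ext))
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  img * 65535
}
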