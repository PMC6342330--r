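# Full pipeline orchestration for one sub-grid: preprocessing scalars,
# gridding, per-cell clustering, adaptive refinement and quantification.
# The gridding and clustering raster is the median-denoised sum of the
# two channels; quantification always uses the denoised native-scale
# channels. The printed contrast-enhancement rule can be routed into the
# gridding raster via `applyEnhancement` (see the vignette for why it is
# off by default). With a fixed configuration the improved modes are
# fully deterministic; the baselines draw their random initial pixels
# from the configured seed.

#' Pipeline configuration
#'
#' All tunable knobs of [runPipeline()] with their defaults.
#'
#' @param medianSize median filter window (odd, >= 3).
#' @param bgTrials,bgWindows,bgWindowSize background-estimation controls
#'   (trials m, windows per trial, window side).
#' @param markerDrop reconstruction marker drop for gridding.
#' @param bandFrac gap-trim fraction for boundary placement, see
#'   [extractGridLines()].
#' @param sigmaRule Gaussian template sigma as a fraction of the spot
#'   diameter d (default 0.25, i.e. sigma = d/4).
#' @param mFuzz,tol,maxIter clustering controls.
#' @param missingRule `"linear"` or `"area"`, see [flagMissing()].
#' @param circleCenter refine circle anchoring, see [refineSubgrid()].
#' @param applyEnhancement route [enhanceContrast()] into the gridding
#'   raster?
#' @param enhanceBranch,enhanceTarget enhancement controls.
#' @param sFormula spot-size formula, see [gridImage()].
#' @param entropyBins histogram bins of the entropy feature.
#' @param seed integer seed for every stochastic element (background
#'   window draws, baseline initialization).
#' @return named list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(medianSize = 3L, bgTrials = 10L,
                           bgWindows = 12L, bgWindowSize = 10L,
                           markerDrop = 0.1, bandFrac = 0.25,
                           sigmaRule = 0.25,
                           mFuzz = 2, tol = 1e-5, maxIter = 100L,
                           missingRule = "linear",
                           circleCenter = "centroid",
                           applyEnhancement = FALSE,
                           enhanceBranch = "le", enhanceTarget = 10000,
                           sFormula = "mean", entropyBins = 256L,
                           seed = 1L) {
  cfg <- list(medianSize = as.integer(medianSize),
              bgTrials = as.integer(bgTrials),
              bgWindows = as.integer(bgWindows),
              bgWindowSize = as.integer(bgWindowSize),
              markerDrop = markerDrop, bandFrac = bandFrac,
              sigmaRule = sigmaRule,
              mFuzz = mFuzz, tol = tol, maxIter = as.integer(maxIter),
              missingRule = match.arg(missingRule, c("linear", "area")),
              circleCenter = match.arg(circleCenter,
                                       c("centroid", "cell")),
              applyEnhancement = isTRUE(applyEnhancement),
              enhanceBranch = match.arg(enhanceBranch, c("le", "gt")),
              enhanceTarget = enhanceTarget,
              sFormula = match.arg(sFormula, c("mean", "sum")),
              entropyBins = as.integer(entropyBins),
              seed = as.integer(seed))
  class(cfg) <- "PipelineConfig"
  cfg
}

# Round the estimated diameter to the template's odd integer size (>= 3).
#' @noRd
oddTemplateSize <- function(d) {
  o <- round(d)
  if (o %% 2L == 0L) o <- o - 1L
  max(3L, as.integer(o))
}

#' Run the full segmentation + quantification pipeline on one sub-grid
#'
#' Stages: contrast score and background gray level on the channel sum;
#' median denoising; gridding into spot cells; per-cell two-class
#' clustering in the selected mode; adaptive refinement (circle-noise
#' removal, missing-spot flags) for the improved modes; per-spot
#' background-corrected expression (M, A) and quality indices. The
#' adaptive refinement is one of the improvements, so the traditional
#' baselines (`km`, `fcm`) are quantified on their raw cluster masks.
#'
#' @param cy3 Cy3 channel matrix, or a [MicroarraySubgrid-class] (then
#'   `cy5` is taken from it).
#' @param cy5 Cy5 channel matrix, or NULL for single-channel input.
#' @param mode clustering mode: `"ikm"`, `"ifcm"`, `"km"`, `"fcm"`.
#' @param config a [pipelineConfig()] list.
#' @return a [SubgridSegmentation-class].
#' @examples
#' \donttest{
#' sg <- generateSubgrid(qualityPreset("good", nRows = 4, nCols = 4))
#' res <- runPipeline(sg, mode = "ikm")
#' head(spotQuant(res))
#' }
#' @export
runPipeline <- function(cy3, cy5 = NULL,
                        mode = c("ikm", "ifcm", "km", "fcm"),
                        config = pipelineConfig()) {
  mode <- match.arg(mode)
  if (is(cy3, "MicroarraySubgrid")) {
    cy5 <- cy3@cy5
    cy3 <- cy3@cy3
  }
  assertMatrixImage(cy3, "cy3")
  twoChannel <- !is.null(cy5)
  if (twoChannel) {
    assertMatrixImage(cy5, "cy5")
    if (!identical(dim(cy3), dim(cy5)))
      msgStop("microseg_parameter_error",
              "channel images must share dimensions (stage: input)")
  } else cy5 <- cy3
  combined <- cy3 + cy5

  cs <- contrastScore(combined)
  k <- estimateBackground(combined, m = config$bgTrials,
                          windowsPerTrial = config$bgWindows,
                          windowSize = config$bgWindowSize,
                          seed = config$seed)
  segRaster <- denoiseMedian(combined, config$medianSize)
  gridRaster <- if (config$applyEnhancement)
    denoiseMedian(enhanceContrast(combined, cs$C, k,
                                  target = config$enhanceTarget,
                                  branch = config$enhanceBranch),
                  config$medianSize)
  else segRaster
  den3 <- denoiseMedian(cy3, config$medianSize)
  den5 <- denoiseMedian(cy5, config$medianSize)

  grid <- gridImage(gridRaster, markerDrop = config$markerDrop,
                    sFormula = config$sFormula,
                    bandFrac = config$bandFrac)
  cells <- gridCells(grid)
  dOdd <- oddTemplateSize(spotDiameter(grid))
  template <- gaussianTemplate(dOdd, sigma = dOdd * config$sigmaRule)

  # improved modes cluster the denoised raster (denoising is part of the
  # proposed preprocessing); the traditional baselines cluster the raw
  # pixel intensities, as the methods they stand for do
  clusterRaster <- if (mode %in% c("ikm", "ifcm")) segRaster else combined

  masks <- vector("list", nrow(cells))
  totIter <- 0L
  for (idx in seq_len(nrow(cells))) {
    seg <- segmentCell(clusterRaster, cells[idx, ], k, mode = mode,
                       template = template, mFuzz = config$mFuzz,
                       tol = config$tol, maxIter = config$maxIter,
                       entropyBins = config$entropyBins,
                       seed = config$seed + idx)
    masks[[idx]] <- seg$mask
    totIter <- totIter + seg$fit@nIter
  }

  # adaptive adjustment is part of the improved methods; the traditional
  # baselines keep their raw cluster masks
  ref <- if (mode %in% c("ikm", "ifcm"))
    refineSubgrid(masks, grid, rule = config$missingRule,
                  circleCenter = config$circleCenter)
  else {
    nFB <- vapply(masks, sum, numeric(1))
    list(masks = masks,
         report = data.frame(
           row = cells$row, col = cells$col,
           nS = vapply(masks, length, numeric(1)),
           nFBefore = nFB, nF = nFB, nC = NA_real_, removed = 0L,
           isMissing = FALSE),
         s = spotSize(grid))
  }

  fullMask <- matrix(0L, nrow(cy3), ncol(cy3))
  for (idx in seq_len(nrow(cells))) {
    cell <- cells[idx, ]
    fullMask[cell$r0:cell$r1, cell$c0:cell$c1] <-
      fullMask[cell$r0:cell$r1, cell$c0:cell$c1] +
      as.integer(ref$masks[[idx]])
  }
  fullMask <- pmin(fullMask, 1L)
  bgk0 <- mean(segRaster[fullMask == 0L])

  quant <- vector("list", nrow(cells))
  for (idx in seq_len(nrow(cells))) {
    cell <- cells[idx, ]
    rows <- cell$r0:cell$r1; cols <- cell$c0:cell$c1
    m <- ref$masks[[idx]]
    q <- extractExpression(m, den3[rows, cols, drop = FALSE],
                           den5[rows, cols, drop = FALSE],
                           isMissing = ref$report$isMissing[idx])
    seg <- segRaster[rows, cols, drop = FALSE]
    fg <- m > 0
    q$FMean <- if (any(fg)) mean(seg[fg]) else NA_real_
    q$BMean <- if (any(!fg)) mean(seg[!fg]) else NA_real_
    q$BSD <- if (sum(!fg) > 1L) sd(seg[!fg]) else NA_real_
    quant[[idx]] <- cbind(data.frame(row = cell$row, col = cell$col), q)
  }
  quant <- do.call(rbind, quant)
  quant <- cbind(quant,
                 qualityIndex(quant$FMean, quant$BMean, quant$BSD, bgk0))

  new("SubgridSegmentation",
      mask = fullMask, grid = grid, quant = quant,
      report = ref$report,
      stats = list(C = cs$C, k = k,
                   h = length(hLines(grid)), v = length(vLines(grid)),
                   d = spotDiameter(grid), s = spotSize(grid),
                   bgk0 = bgk0, iterations = totIter,
                   twoChannel = twoChannel),
      mode = mode, config = unclass(config))
}
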