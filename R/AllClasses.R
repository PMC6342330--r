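# S4 containers for the segmentation pipeline.

setClassUnion("listOrNULL", c("list", "NULL"))
setClassUnion("matrixOrNULL", c("matrix", "NULL"))

#' Parameters of the synthetic sub-grid generator
#'
#' Describes one synthetic two-channel microarray sub-grid: layout, spot
#' geometry, the mixture of spot shapes, channel intensity levels, noise,
#' and the seed that makes generation reproducible.
#'
#' @slot nRows,nCols number of spot rows / columns.
#' @slot cellPx cell pitch in pixels (spot-to-spot spacing).
#' @slot spotDiameterPx nominal spot diameter in pixels.
#' @slot shapeMix named numeric proportions over
#'   `c("circle","donut","comet","irregular","missing")`; non-negative,
#'   summing to 1.
#' @slot fgLevel length-2 named numeric `c(cy3=,cy5=)`: mean foreground
#'   intensity per channel (16-bit counts).
#' @slot bgLevel mean background intensity (counts).
#' @slot noiseSigma additive Gaussian noise standard deviation (counts).
#' @slot mSd standard deviation of the per-spot true log2-ratio draw
#'   (0 = all spots share the ratio implied by `fgLevel`).
#' @slot qualityPreset one of `"good"`, `"normal"`, `"poor"`, or
#'   `"custom"`.
#' @slot seed integer RNG seed.
#'
#' @seealso [synthParams()], [qualityPreset()], [generateSubgrid()]
#' @exportClass SynthParams
setClass("SynthParams",
  representation(
    nRows = "integer", nCols = "integer",
    cellPx = "integer", spotDiameterPx = "numeric",
    shapeMix = "numeric",
    fgLevel = "numeric", bgLevel = "numeric",
    noiseSigma = "numeric", mSd = "numeric",
    qualityPreset = "character", seed = "integer"
  )
)

setValidity("SynthParams", function(object) {
  msgs <- character()
  shapes <- c("circle", "donut", "comet", "irregular", "missing")
  if (!identical(sort(names(object@shapeMix)), sort(shapes)))
    msgs <- c(msgs, sprintf("shapeMix must be named over {%s}",
                            paste(shapes, collapse = ", ")))
  else {
    if (any(object@shapeMix < 0))
      msgs <- c(msgs, "shapeMix proportions must be non-negative")
    if (abs(sum(object@shapeMix) - 1) > 1e-8)
      msgs <- c(msgs, "shapeMix proportions must sum to 1")
  }
  if (object@nRows < 1L || object@nCols < 1L)
    msgs <- c(msgs, "nRows and nCols must be positive")
  if (!(object@spotDiameterPx > 0 && object@spotDiameterPx < object@cellPx))
    msgs <- c(msgs, "need 0 < spotDiameterPx < cellPx")
  if (length(object@fgLevel) != 2L)
    msgs <- c(msgs, "fgLevel must have one entry per channel (cy3, cy5)")
  if (!(object@bgLevel >= 0 && all(object@fgLevel > object@bgLevel)))
    msgs <- c(msgs, "need fgLevel > bgLevel >= 0")
  if (object@noiseSigma < 0) msgs <- c(msgs, "noiseSigma must be >= 0")
  if (object@mSd < 0) msgs <- c(msgs, "mSd must be >= 0")
  if (length(msgs)) msgs else TRUE
})

#' Synthetic two-channel sub-grid with ground truth
#'
#' The generated Cy3/Cy5 intensity rasters together with the pixel-level
#' truth mask, the per-spot expression table (`row`, `col`, `shape`,
#' `trueM`, `isMissing`), and the true grid-line coordinates.
#'
#' @slot cy3,cy5 numeric intensity matrices (16-bit scale).
#' @slot mask integer truth matrix (1 = spot pixel).
#' @slot expression per-spot truth `data.frame`.
#' @slot hLines,vLines true interior grid-line coordinates (pixel borders,
#'   half-integer, 1-based).
#' @slot params the [SynthParams-class] that produced the object.
#' @exportClass MicroarraySubgrid
setClass("MicroarraySubgrid",
  representation(
    cy3 = "matrix", cy5 = "matrix", mask = "matrix",
    expression = "data.frame",
    hLines = "numeric", vLines = "numeric",
    params = "SynthParams"
  )
)

setValidity("MicroarraySubgrid", function(object) {
  msgs <- character()
  if (!identical(dim(object@cy3), dim(object@cy5)))
    msgs <- c(msgs, "cy3 and cy5 must have identical dimensions")
  if (!identical(dim(object@cy3), dim(object@mask)))
    msgs <- c(msgs, "mask must have the same dimensions as the images")
  if (length(msgs)) msgs else TRUE
})

#' Gridding result for one sub-grid
#'
#' Interior grid-line coordinates on both axes, the boundary-line pairs
#' delimiting each spot band, the estimated spot diameter `d`, the rough
#' spot size `s`, and the table of spot cells the lines induce.
#'
#' @slot hLines,vLines sorted interior grid-line coordinates (pixels;
#'   half-integers denote pixel borders).
#' @slot hBounds,vBounds boundary-line coordinates; even counts, pairing
#'   up around each spot band.
#' @slot d estimated spot diameter (mean grid pitch, pixels).
#' @slot s rough spot size (mean boundary-pair width, pixels).
#' @slot cells `data.frame` with one row per spot cell: `row`, `col`,
#'   `r0`, `r1`, `c0`, `c1` (inclusive 1-based spans), `rc`, `cc`
#'   (center pixel).
#' @exportClass SpotGrid
setClass("SpotGrid",
  representation(
    hLines = "numeric", vLines = "numeric",
    hBounds = "numeric", vBounds = "numeric",
    d = "numeric", s = "numeric",
    cells = "data.frame"
  )
)

setValidity("SpotGrid", function(object) {
  msgs <- character()
  if (is.unsorted(object@hLines, strictly = TRUE) ||
      is.unsorted(object@vLines, strictly = TRUE))
    msgs <- c(msgs, "grid lines must be strictly increasing")
  if (length(object@hBounds) %% 2L != 0L ||
      length(object@vBounds) %% 2L != 0L)
    msgs <- c(msgs, "boundary lines must pair up (even counts)")
  if (!(object@d > 0) || !(object@s > 0))
    msgs <- c(msgs, "d and s must be positive")
  if (length(msgs)) msgs else TRUE
})

#' Two-class clustering fit for one spot cell
#'
#' @slot labels integer vector in `{1, 2}` (1 = background-initialized
#'   cluster, 2 = foreground-initialized cluster), one per pixel.
#' @slot centers 2 x p matrix of cluster centers in feature space.
#' @slot membership n x 2 fuzzy membership matrix (FCM only, else NULL);
#'   rows sum to 1.
#' @slot costTrace objective value per iteration (non-increasing).
#' @slot nIter iterations used.
#' @slot mode `"ikm"`, `"ifcm"`, `"km"`, or `"fcm"`.
#' @exportClass ClusterFit
setClass("ClusterFit",
  representation(
    labels = "integer", centers = "matrix",
    membership = "matrixOrNULL",
    costTrace = "numeric", nIter = "integer", mode = "character"
  )
)

setValidity("ClusterFit", function(object) {
  msgs <- character()
  if (!all(object@labels %in% c(1L, 2L)))
    msgs <- c(msgs, "labels must be in {1, 2}")
  if (nrow(object@centers) != 2L)
    msgs <- c(msgs, "centers must have two rows")
  if (!is.null(object@membership)) {
    if (nrow(object@membership) != length(object@labels))
      msgs <- c(msgs, "membership must have one row per pixel")
    else if (max(abs(rowSums(object@membership) - 1)) > 1e-8)
      msgs <- c(msgs, "membership rows must sum to 1")
  }
  if (length(object@costTrace) > 1L &&
      any(diff(object@costTrace) > 1e-9 * max(1, object@costTrace[1L])))
    msgs <- c(msgs, "costTrace must be non-increasing")
  if (length(msgs)) msgs else TRUE
})

#' Full segmentation + quantification result for one sub-grid
#'
#' @slot mask integer full-image segmentation mask (1 = foreground).
#' @slot grid the [SpotGrid-class] used.
#' @slot quant per-spot quantification `data.frame` (counts, corrected
#'   intensities, M, A, quality components, missing flag).
#' @slot report per-spot refinement report (`nS`, `nFBefore`, `nF`, `nC`,
#'   `removed`, `isMissing`).
#' @slot stats named list of pipeline scalars (contrast C, background k,
#'   line counts h/v, d, s, bgk0, iteration totals).
#' @slot mode clustering mode used.
#' @slot config pipeline configuration list.
#' @exportClass SubgridSegmentation
setClass("SubgridSegmentation",
  representation(
    mask = "matrix", grid = "SpotGrid",
    quant = "data.frame", report = "data.frame",
    stats = "list", mode = "character", config = "list"
  )
)
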