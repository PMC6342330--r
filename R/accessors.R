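# Accessors and show methods.

#' @describeIn MicroarraySubgrid Cy3 (red) channel raster.
#' @param x a `MicroarraySubgrid`.
#' @export
setMethod("cy3Image", "MicroarraySubgrid", function(x) x@cy3)

#' @describeIn MicroarraySubgrid Cy5 (green) channel raster.
#' @export
setMethod("cy5Image", "MicroarraySubgrid", function(x) x@cy5)

#' @describeIn MicroarraySubgrid pixel-level truth mask (1 = spot).
#' @export
setMethod("truthMask", "MicroarraySubgrid", function(x) x@mask)

#' @describeIn MicroarraySubgrid per-spot truth table.
#' @export
setMethod("truthTable", "MicroarraySubgrid", function(x) x@expression)

#' @describeIn MicroarraySubgrid true horizontal grid-line coordinates.
#' @export
setMethod("hLines", "MicroarraySubgrid", function(x) x@hLines)

#' @describeIn MicroarraySubgrid true vertical grid-line coordinates.
#' @export
setMethod("vLines", "MicroarraySubgrid", function(x) x@vLines)

#' @describeIn SpotGrid horizontal (row) interior grid-line coordinates.
#' @param x a `SpotGrid`.
#' @export
setMethod("hLines", "SpotGrid", function(x) x@hLines)

#' @describeIn SpotGrid vertical (column) interior grid-line coordinates.
#' @export
setMethod("vLines", "SpotGrid", function(x) x@vLines)

#' @describeIn SpotGrid boundary-line pairs, `list(h = , v = )`.
#' @export
setMethod("boundaryLines", "SpotGrid",
          function(x) list(h = x@hBounds, v = x@vBounds))

#' @describeIn SpotGrid estimated spot diameter d (pixels).
#' @export
setMethod("spotDiameter", "SpotGrid", function(x) x@d)

#' @describeIn SpotGrid rough spot size s (pixels).
#' @export
setMethod("spotSize", "SpotGrid", function(x) x@s)

#' @describeIn SpotGrid spot-cell table (spans and centers).
#' @export
setMethod("gridCells", "SpotGrid", function(x) x@cells)

#' @describeIn ClusterFit per-pixel labels (1 = background cluster).
#' @param x a `ClusterFit`.
#' @export
setMethod("clusterLabels", "ClusterFit", function(x) x@labels)

#' @describeIn ClusterFit cluster centers (2 x p).
#' @export
setMethod("clusterCenters", "ClusterFit", function(x) x@centers)

#' @describeIn ClusterFit fuzzy membership matrix (NULL for K-means).
#' @export
setMethod("membershipMatrix", "ClusterFit", function(x) x@membership)

#' @describeIn ClusterFit objective value per iteration.
#' @export
setMethod("costTrace", "ClusterFit", function(x) x@costTrace)

#' @describeIn SubgridSegmentation full-image segmentation mask.
#' @param x a `SubgridSegmentation`.
#' @export
setMethod("segMask", "SubgridSegmentation", function(x) x@mask)

#' @describeIn SubgridSegmentation per-spot quantification table.
#' @export
setMethod("spotQuant", "SubgridSegmentation", function(x) x@quant)

#' @describeIn SubgridSegmentation per-spot refinement report.
#' @export
setMethod("refineReport", "SubgridSegmentation", function(x) x@report)

#' @describeIn SubgridSegmentation pipeline scalar diagnostics.
#' @export
setMethod("pipelineStats", "SubgridSegmentation", function(x) x@stats)

setMethod("show", "SynthParams", function(object) {
  cat("SynthParams [", object@qualityPreset, "]\n", sep = "")
  cat(sprintf("  layout: %d x %d spots, pitch %d px, spot diameter %.1f px\n",
              object@nRows, object@nCols, object@cellPx,
              object@spotDiameterPx))
  cat(sprintf("  levels: fg (%s, %s), bg %s, noise sd %s, mSd %s\n",
              fmtNum(object@fgLevel[1]), fmtNum(object@fgLevel[2]),
              fmtNum(object@bgLevel), fmtNum(object@noiseSigma),
              fmtNum(object@mSd)))
  mix <- paste(sprintf("%s %.2f", names(object@shapeMix), object@shapeMix),
               collapse = ", ")
  cat("  shapes:", mix, "\n")
  cat("  seed:", object@seed, "\n")
})

setMethod("show", "MicroarraySubgrid", function(object) {
  cat(sprintf("MicroarraySubgrid: %d x %d px, %d x %d spots (%s preset)\n",
              nrow(object@cy3), ncol(object@cy3),
              object@params@nRows, object@params@nCols,
              object@params@qualityPreset))
  cat(sprintf("  truth: %d spot pixels, %d missing spot(s)\n",
              sum(object@mask), sum(object@expression$isMissing)))
})

setMethod("show", "SpotGrid", function(object) {
  cat(sprintf("SpotGrid: %d H x %d V interior lines, %d cells\n",
              length(object@hLines), length(object@vLines),
              nrow(object@cells)))
  cat(sprintf("  spot diameter d = %.2f px, rough spot size s = %.2f px\n",
              object@d, object@s))
})

setMethod("show", "ClusterFit", function(object) {
  cat(sprintf("ClusterFit [%s]: %d pixels, %d foreground, %d iteration(s)\n",
              object@mode, length(object@labels),
              sum(object@labels == 2L), object@nIter))
})

setMethod("show", "SubgridSegmentation", function(object) {
  cat(sprintf("SubgridSegmentation [%s]: %d x %d px, %d spots (%d missing)\n",
              object@mode, nrow(object@mask), ncol(object@mask),
              nrow(object@quant), sum(object@quant$isMissing)))
  cat(sprintf("  foreground pixels: %d; C = %s, k = %s\n",
              sum(object@mask),
              fmtNum(object@stats$C), fmtNum(object@stats$k)))
})
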