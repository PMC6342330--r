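# File output for pipeline results: mask PNG, grid/cell/quant/report
# CSVs, and a JSON run manifest.

#' Write pipeline outputs to a directory
#'
#' Writes `mask.png` (8-bit 0/255), `grid.csv` (line type and
#' coordinate), `cells.csv`, `quant.csv` (floats at 6 significant
#' digits), `report.csv`, and `manifest.json` recording the mode,
#' configuration, scalar diagnostics, package version and the emitted
#' files.
#'
#' @param x a [SubgridSegmentation-class].
#' @param dir output directory (created if absent).
#' @return invisibly, the manifest as a list.
#' @export
writePipelineOutputs <- function(x, dir) {
  stopifnot(is(x, "SubgridSegmentation"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  png::writePNG(x@mask + 0, file.path(dir, "mask.png"))
  bounds <- boundaryLines(x@grid)
  gridDf <- rbind(
    data.frame(type = "H", coordinate = hLines(x@grid)),
    data.frame(type = "V", coordinate = vLines(x@grid)),
    data.frame(type = "BH0", coordinate = bounds$h),
    data.frame(type = "BV0", coordinate = bounds$v))
  write.csv(gridDf, file.path(dir, "grid.csv"), row.names = FALSE)
  write.csv(gridCells(x@grid), file.path(dir, "cells.csv"),
            row.names = FALSE)
  quant <- spotQuant(x)
  isNum <- vapply(quant, is.double, logical(1))
  quant[isNum] <- lapply(quant[isNum], signif, digits = 6)
  write.csv(quant, file.path(dir, "quant.csv"), row.names = FALSE)
  write.csv(refineReport(x), file.path(dir, "report.csv"),
            row.names = FALSE)
  manifest <- list(
    mode = x@mode,
    config = x@config,
    stats = pipelineStats(x),
    package = as.character(utils::packageVersion("microseg")),
    files = c("mask.png", "grid.csv", "cells.csv", "quant.csv",
              "report.csv"))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
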