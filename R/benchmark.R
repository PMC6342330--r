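# Multi-image benchmark: generate seeded synthetic sub-grids across the
# quality presets, run the requested clustering modes, and aggregate the
# pixel-level metrics against the generator's truth masks, plus the
# special-expression counts.

#' Benchmark segmentation modes on synthetic sub-grids
#'
#' Generates one sub-grid per `(preset, seed)` pair, runs every mode on
#' it, scores the predicted masks against ground truth, and averages
#' accuracy, sensitivity and specificity per mode.
#'
#' @param presets character vector of [qualityPreset()] names.
#' @param seeds integer seeds (one image per preset per seed).
#' @param modes clustering modes to benchmark.
#' @param nRows,nCols spot layout of the generated images.
#' @param config a [pipelineConfig()].
#' @return list with `metrics` (one row per mode: mean `acc`, `se`,
#'   `sp`), `perImage` (per image x mode), and `special` (per-mode
#'   special expression counts, summed over images).
#' @examples
#' \donttest{
#' bm <- runBenchmark(presets = "good", seeds = 1, modes = "ikm",
#'                    nRows = 4, nCols = 4)
#' bm$metrics
#' }
#' @export
runBenchmark <- function(presets = c("good", "normal", "poor"),
                         seeds = 1:3,
                         modes = c("km", "ikm", "fcm", "ifcm"),
                         nRows = 10L, nCols = 10L,
                         config = pipelineConfig()) {
  rows <- list()
  for (preset in presets) {
    for (sd in seeds) {
      sg <- generateSubgrid(qualityPreset(preset, nRows = nRows,
                                          nCols = nCols, seed = sd))
      for (mode in modes) {
        res <- runPipeline(sg, mode = mode, config = config)
        ev <- evaluateMask(segMask(res), truthMask(sg))
        sp <- specialExpressionCount(spotQuant(res))
        rows[[length(rows) + 1L]] <- data.frame(
          preset = preset, seed = sd, mode = mode,
          acc = ev$acc, se = ev$se, sp = ev$sp,
          nAbove = sp[["nAbove"]], nBelow = sp[["nBelow"]])
      }
    }
  }
  perImage <- do.call(rbind, rows)
  agg <- function(col) vapply(modes, function(m)
    mean(perImage[[col]][perImage$mode == m]), numeric(1))
  metrics <- data.frame(mode = modes, acc = agg("acc"),
                        se = agg("se"), sp = agg("sp"))
  rownames(metrics) <- NULL
  special <- data.frame(
    mode = modes,
    nAbove = vapply(modes, function(m)
      sum(perImage$nAbove[perImage$mode == m]), numeric(1)),
    nBelow = vapply(modes, function(m)
      sum(perImage$nBelow[perImage$mode == m]), numeric(1)))
  rownames(special) <- NULL
  list(metrics = metrics, perImage = perImage, special = special)
}
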