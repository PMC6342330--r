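# Expression extraction and quantitative evaluation. Per spot cell the
# background-corrected channel intensities are I_cy3 = R_fore - R_back
# and I_cy5 = G_fore - G_back (means over the foreground / local
# background pixels of the cell), giving the log ratio
# M = log2(I_cy3 / I_cy5) and mean log intensity
# A = (1/2) log2(I_cy3 * I_cy5). Pixel-level segmentation quality against
# a truth mask uses acc = (TP+TN)/total, se = TP/(TP+FN) and
# sp = TP/(TP+FP) — sp exactly as printed, i.e. the precision of the
# foreground call.

#' Background-corrected expression of one spot cell
#'
#' Foreground and background means per channel over the mask partition of
#' the cell; background pixels are the cell's non-foreground pixels
#' (local background). `M` and `A` are `NA` for missing spots, empty
#' foregrounds, and non-positive corrected intensities.
#'
#' @param mask logical (or 0/1) foreground mask of the cell.
#' @param cy3,cy5 numeric cell rasters of the two channels, same shape
#'   as `mask`.
#' @param isMissing was the spot flagged missing by refinement?
#' @return one-row `data.frame`: `NFore`, `NBack`, `RFore`, `RBack`,
#'   `GFore`, `GBack`, `Icy3`, `Icy5`, `M`, `A`, `isMissing`.
#' @examples
#' m <- matrix(c(TRUE, FALSE), 1)
#' extractExpression(m, matrix(c(200, 100), 1), matrix(c(150, 100), 1))$M
#' @export
extractExpression <- function(mask, cy3, cy5, isMissing = FALSE) {
  if (!identical(dim(mask), dim(cy3)) || !identical(dim(cy3), dim(cy5)))
    msgStop("microseg_parameter_error",
            "mask and channel cells must share dimensions")
  fg <- mask > 0
  nF <- sum(fg); nB <- sum(!fg)
  if (isMissing || nF == 0L || nB == 0L) {
    return(data.frame(
      NFore = nF, NBack = nB,
      RFore = if (nF) mean(cy3[fg]) else NA_real_,
      RBack = if (nB) mean(cy3[!fg]) else NA_real_,
      GFore = if (nF) mean(cy5[fg]) else NA_real_,
      GBack = if (nB) mean(cy5[!fg]) else NA_real_,
      Icy3 = NA_real_, Icy5 = NA_real_, M = NA_real_, A = NA_real_,
      isMissing = isMissing || nF == 0L))
  }
  RFore <- mean(cy3[fg]); RBack <- mean(cy3[!fg])
  GFore <- mean(cy5[fg]); GBack <- mean(cy5[!fg])
  Icy3 <- RFore - RBack
  Icy5 <- GFore - GBack
  ok <- Icy3 > 0 && Icy5 > 0
  data.frame(
    NFore = nF, NBack = nB, RFore = RFore, RBack = RBack,
    GFore = GFore, GBack = GBack, Icy3 = Icy3, Icy5 = Icy5,
    M = if (ok) log2(Icy3 / Icy5) else NA_real_,
    A = if (ok) 0.5 * log2(Icy3 * Icy5) else NA_real_,
    isMissing = FALSE)
}

#' Per-spot quality index components
#'
#' `q_sig_noise = F_mean / (F_mean + B_mean)`;
#' `q_bkg1` is the local background variability ratio `BSD / B_mean`
#' normalized by its sub-grid maximum and complemented;
#' `q_bkg2` is the local background level ratio `bgk0 / (bgk0 + B_mean)`
#' normalized by its sub-grid maximum; and
#' `q_index` is the geometric mean of the three. All components lie in
#' `[0, 1]`; spots with `B_mean = 0` get `NA` components.
#'
#' @param FMean,BMean,BSD numeric vectors (one entry per spot): mean
#'   foreground, mean local background, and local background standard
#'   deviation.
#' @param bgk0 global background mean of the sub-grid.
#' @return `data.frame` with `qSigNoise`, `qBkg1`, `qBkg2`, `qIndex`.
#' @export
qualityIndex <- function(FMean, BMean, BSD, bgk0) {
  bad <- !is.finite(BMean) | BMean == 0 | !is.finite(FMean)
  qsn <- ifelse(bad, NA_real_, FMean / (FMean + BMean))
  ratio1 <- ifelse(bad, NA_real_, BSD / BMean)
  q1 <- if (all(is.na(ratio1)) || max(ratio1, na.rm = TRUE) == 0)
    ifelse(bad, NA_real_, 1)
  else 1 - ratio1 / max(ratio1, na.rm = TRUE)
  ratio2 <- ifelse(bad, NA_real_, bgk0 / (bgk0 + BMean))
  q2 <- if (all(is.na(ratio2)) || max(ratio2, na.rm = TRUE) == 0)
    ratio2
  else ratio2 / max(ratio2, na.rm = TRUE)
  data.frame(qSigNoise = qsn, qBkg1 = q1, qBkg2 = q2,
             qIndex = (qsn * q1 * q2)^(1 / 3))
}

#' Pixel-level confusion counts of a segmentation against truth
#'
#' Foreground is the positive class. `acc = (TP+TN)/total`,
#' `se = TP/(TP+FN)` (sensitivity / recall of spot pixels) and
#' `sp = TP/(TP+FP)` (as printed — the precision of the foreground
#' call).
#'
#' @param pred predicted mask (logical or 0/1 matrix).
#' @param truth truth mask, same shape.
#' @return list of class `EvalCounts`: `TP`, `TN`, `FP`, `FN`, `acc`,
#'   `se`, `sp`.
#' @examples
#' evaluateMask(matrix(c(1, 0), 1), matrix(c(1, 1), 1))$se
#' @export
evaluateMask <- function(pred, truth) {
  if (!identical(dim(pred), dim(truth)))
    msgStop("microseg_parameter_error",
            "pred and truth masks must share dimensions")
  p <- pred > 0; t <- truth > 0
  TP <- sum(p & t); TN <- sum(!p & !t)
  FP <- sum(p & !t); FN <- sum(!p & t)
  structure(list(
    TP = TP, TN = TN, FP = FP, FN = FN,
    acc = (TP + TN) / (TP + TN + FP + FN),
    se = if (TP + FN > 0) TP / (TP + FN) else NA_real_,
    sp = if (TP + FP > 0) TP / (TP + FP) else NA_real_),
    class = "EvalCounts")
}

#' Count special (extreme) expression values
#'
#' Expression ratios between -2 and +2 are considered normal; values
#' beyond the bound flag special genes (or noise).
#'
#' @param M numeric vector of log2 ratios, or a quantification
#'   `data.frame` with an `M` column.
#' @param bound threshold (default 2).
#' @return named integer vector `c(nAbove =, nBelow =)` counting non-NA
#'   `M > bound` and `M < -bound`.
#' @examples
#' specialExpressionCount(c(2.5, -3, 0, NA))
#' @export
specialExpressionCount <- function(M, bound = 2) {
  if (is.data.frame(M)) M <- M$M
  c(nAbove = sum(M > bound, na.rm = TRUE),
    nBelow = sum(M < -bound, na.rm = TRUE))
}
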