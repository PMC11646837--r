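#' Composite detection-loss configuration
#'
#' Fixed component weights (classification 0.5, localization 0.05) and a
#' scale-dependent objectness gain: the small:medium:large gain ratio is
#' 4:1:0.4 of a base value. Only the ratio is fixed by the method; the
#' base gain and the area thresholds (detection-convention defaults of
#' 32^2 and 96^2 px^2) are configurable.
#'
#' @param wCls Classification weight, default 0.5.
#' @param wBox Localization weight, default 0.05.
#' @param objGainBase Base objectness gain, default 1.
#' @param gainRatio Small/medium/large multipliers, default c(4, 1, 0.4).
#' @param scaleThresholds Area cut points in px^2, default c(32^2, 96^2).
#' @return List of class \code{lossConfig}.
#' @export
lossConfig <- function(wCls = 0.5, wBox = 0.05, objGainBase = 1,
                       gainRatio = c(4, 1, 0.4),
                       scaleThresholds = c(32^2, 96^2)) {
  if (wCls <= 0 || wBox <= 0 || objGainBase <= 0)
    stop("loss weights must be positive")
  if (length(gainRatio) != 3L || any(gainRatio <= 0))
    stop("gainRatio must be three positive multipliers")
  if (length(scaleThresholds) != 2L || diff(scaleThresholds) <= 0)
    stop("scaleThresholds must be increasing (small, large) cut points")
  structure(list(wCls = wCls, wBox = wBox, objGainBase = objGainBase,
                 gainRatio = gainRatio, scaleThresholds = scaleThresholds),
            class = "lossConfig")
}

#' Scale-dependent objectness gain
#'
#' Piecewise-constant gain by target area: 4x the base below the small
#' threshold, 1x between the thresholds, 0.4x above.
#'
#' @param truthArea Ground-truth box area in px^2 (> 0; vectorized).
#' @param cfg A [lossConfig()].
#' @return Gain value(s).
#' @export
scaleGain <- function(truthArea, cfg = lossConfig()) {
  if (any(truthArea <= 0)) stop("target area must be positive")
  idx <- 1L + (truthArea >= cfg$scaleThresholds[1]) +
    (truthArea > cfg$scaleThresholds[2])
  cfg$objGainBase * cfg$gainRatio[idx]
}

#' Complete-IoU localization loss
#'
#' 1 - CIoU, where CIoU subtracts from IoU a normalized center-distance
#' penalty (squared center distance over the squared diagonal of the
#' smallest enclosing box) and an aspect-ratio penalty
#' v = (4/pi^2)(atan(w1/h1) - atan(w2/h2))^2 weighted by
#' alpha = v / ((1 - IoU) + v). The loss lies in [0, 2] and is 0 iff the
#' boxes coincide.
#'
#' @param pred,truth Boxes (x_min, y_min, x_max, y_max).
#' @return Loss value in [0, 2].
#' @export
ciouLoss <- function(pred, truth) {
  p <- unlist(pred[c("x_min", "y_min", "x_max", "y_max")])
  t <- unlist(truth[c("x_min", "y_min", "x_max", "y_max")])
  .checkBox(p); .checkBox(t)
  i <- iou(p, t)
  cx1 <- (p["x_min"] + p["x_max"]) / 2; cy1 <- (p["y_min"] + p["y_max"]) / 2
  cx2 <- (t["x_min"] + t["x_max"]) / 2; cy2 <- (t["y_min"] + t["y_max"]) / 2
  rho2 <- (cx1 - cx2)^2 + (cy1 - cy2)^2
  ex <- max(p["x_max"], t["x_max"]) - min(p["x_min"], t["x_min"])
  ey <- max(p["y_max"], t["y_max"]) - min(p["y_min"], t["y_min"])
  c2 <- ex^2 + ey^2
  w1 <- p["x_max"] - p["x_min"]; h1 <- p["y_max"] - p["y_min"]
  w2 <- t["x_max"] - t["x_min"]; h2 <- t["y_max"] - t["y_min"]
  v <- (4 / pi^2) * (atan(w1 / h1) - atan(w2 / h2))^2
  alpha <- if (v == 0) 0 else v / ((1 - i) + v)
  unname(1 - (i - rho2 / c2 - alpha * v))
}

#' Cross-entropy classification loss
#'
#' -sum(p_gt * log(p_c)) with predicted probabilities clamped away from 0
#' for numerical safety.
#'
#' @param pGt Target class distribution (typically one-hot).
#' @param pC Predicted class probabilities.
#' @param eps Clamp floor, default 1e-12.
#' @return Non-negative scalar.
#' @export
classificationLoss <- function(pGt, pC, eps = 1e-12) {
  if (length(pGt) != length(pC)) stop("distribution lengths differ")
  -sum(pGt * log(pmin(pmax(pC, eps), 1)))
}

#' Objectness (confidence) loss
#'
#' Binary cross-entropy between the predicted objectness score and the
#' prediction-truth IoU, the soft target that rewards well-localized
#' confident predictions.
#'
#' @param predObj Predicted objectness in [0, 1].
#' @param iouTarget IoU of the matched pair in [0, 1].
#' @param eps Clamp, default 1e-12.
#' @return Non-negative scalar.
#' @export
objectnessLoss <- function(predObj, iouTarget, eps = 1e-12) {
  p <- pmin(pmax(predObj, eps), 1 - eps)
  # exact zero when target and prediction agree at the endpoints
  if (iouTarget == predObj && (iouTarget == 0 || iouTarget == 1)) return(0)
  -(iouTarget * log(p) + (1 - iouTarget) * log(1 - p))
}

#' Composite detection loss over a batch of matched samples
#'
#' (1/N) sum over matched positives of
#' wCls * Lcls + gain(scale) * Lobj + wBox * Lbox, with the classification
#' cross-entropy, IoU-targeted objectness BCE and CIoU localization terms,
#' and the scale-dependent objectness gain at ratio 4:1:0.4.
#'
#' @param batch List of matched samples; each a list with elements
#'   \code{pred} and \code{truth} (boxes), \code{pGt} and \code{pC}
#'   (class distributions) and \code{objectness} (predicted score).
#' @param cfg A [lossConfig()].
#' @return List: total loss plus the averaged weighted components.
#' @export
compositeLoss <- function(batch, cfg = lossConfig()) {
  if (!length(batch)) stop("empty batch: N must be >= 1")
  per <- vapply(batch, function(s) {
    lcls <- classificationLoss(s$pGt, s$pC)
    i <- iou(s$pred, s$truth)
    lobj <- objectnessLoss(s$objectness, i)
    lbox <- ciouLoss(s$pred, s$truth)
    t <- unlist(s$truth[c("x_min", "y_min", "x_max", "y_max")])
    gain <- scaleGain((t["x_max"] - t["x_min"]) * (t["y_max"] - t["y_min"]), cfg)
    c(cls = cfg$wCls * lcls, obj = gain * lobj, box = cfg$wBox * lbox)
  }, numeric(3))
  comp <- rowMeans(per)
  list(total = sum(comp), classification = comp[["cls"]],
       objectness = comp[["obj"]], localization = comp[["box"]],
       n = length(batch))
}

#' Positive-sample assignment predicate
#'
#' The matcher's positive-sample rule, stated as a standalone predicate: a
#' prior box is a positive sample for a target when every side ratio
#' between target and prior is below the fourfold cut, and the target
#' center falls in the prior's grid cell or one of the two adjacent cells
#' nearest the center offset.
#'
#' @param truth Target box.
#' @param anchorW,anchorH Prior dimensions in px.
#' @param cellSize Grid cell size in px.
#' @param anchorCell Integer (col, row) of the prior's cell.
#' @param ratioLimit Side-ratio cut, default 4.
#' @return TRUE when the prior may predict the target.
#' @export
positiveSamplePredicate <- function(truth, anchorW, anchorH, cellSize,
                                    anchorCell, ratioLimit = 4) {
  t <- unlist(truth[c("x_min", "y_min", "x_max", "y_max")])
  w <- t["x_max"] - t["x_min"]; h <- t["y_max"] - t["y_min"]
  ratioOk <- max(w / anchorW, anchorW / w, h / anchorH, anchorH / h) < ratioLimit
  if (!ratioOk) return(FALSE)
  cx <- (t["x_min"] + t["x_max"]) / 2 / cellSize
  cy <- (t["y_min"] + t["y_max"]) / 2 / cellSize
  cells <- list(c(floor(cx), floor(cy)))
  fx <- cx - floor(cx); fy <- cy - floor(cy)
  cells <- c(cells, list(c(floor(cx) + ifelse(fx >= 0.5, 1, -1), floor(cy))),
             list(c(floor(cx), floor(cy) + ifelse(fy >= 0.5, 1, -1))))
  any(vapply(cells, function(cl) all(cl == anchorCell), logical(1)))
}
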