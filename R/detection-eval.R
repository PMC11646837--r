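#' Tissue classes, in increasing severity
#'
#' Frame-level evaluation uses the three classes normal, dysplasia and SCC
#' (squamous cell carcinoma). Severity ordering resolves frames carrying
#' several lesions: the most severe class wins.
#'
#' @return Character vector c("normal", "dysplasia", "SCC").
#' @export
tissueClasses <- function() c("normal", "dysplasia", "SCC")

.severity <- function(cls) match(cls, tissueClasses())

.checkBox <- function(b) {
  if (b["x_min"] >= b["x_max"] || b["y_min"] >= b["y_max"])
    stop("degenerate box: x_min < x_max and y_min < y_max required")
}

#' Intersection over union of two boxes
#'
#' Boxes are numeric vectors (or single-row data.frames) with elements
#' x_min, y_min, x_max, y_max in pixels, half-open on the right/bottom.
#'
#' @param a,b Boxes.
#' @return IoU in [0, 1]; 0 for disjoint boxes.
#' @export
#' @examples
#' iou(c(x_min = 0, y_min = 0, x_max = 2, y_max = 2),
#'     c(x_min = 1, y_min = 1, x_max = 3, y_max = 3))  # 1/7
iou <- function(a, b) {
  a <- unlist(a[c("x_min", "y_min", "x_max", "y_max")])
  b <- unlist(b[c("x_min", "y_min", "x_max", "y_max")])
  .checkBox(a); .checkBox(b)
  iw <- min(a["x_max"], b["x_max"]) - max(a["x_min"], b["x_min"])
  ih <- min(a["y_max"], b["y_max"]) - max(a["y_min"], b["y_min"])
  if (iw <= 0 || ih <= 0) return(0)
  inter <- iw * ih
  areaA <- (a["x_max"] - a["x_min"]) * (a["y_max"] - a["y_min"])
  areaB <- (b["x_max"] - b["x_min"]) * (b["y_max"] - b["y_min"])
  unname(inter / (areaA + areaB - inter))
}

#' Build a frame record
#'
#' @param frameId Unique frame identifier.
#' @param truth data.frame of ground-truth boxes (class, x_min, y_min,
#'   x_max, y_max); zero rows = normal frame.
#' @param pred data.frame of predicted boxes (same columns + confidence).
#' @param modality "WLI" or "NBI".
#' @return List of class \code{frameRecord}.
#' @export
frameRecord <- function(frameId, truth = emptyBoxes(), pred = emptyBoxes(TRUE),
                        modality = "WLI") {
  structure(list(frameId = frameId, truth = truth, pred = pred,
                 modality = modality), class = "frameRecord")
}

#' @rdname frameRecord
#' @param withConfidence Include a confidence column.
#' @export
emptyBoxes <- function(withConfidence = FALSE) {
  df <- data.frame(class = character(), x_min = numeric(), y_min = numeric(),
                   x_max = numeric(), y_max = numeric())
  if (withConfidence) df$confidence <- numeric()
  df
}

#' Frame-level matching of predictions to ground truth
#'
#' Predictions are matched to ground-truth boxes greedily in descending
#' confidence (ties: larger IoU, then lower box index), each truth matched
#' at most once, at IoU >= \code{iouThreshold}. The frame's true class is
#' the most severe ground-truth class (normal if no truth boxes); the
#' predicted class is the most severe class among matched predictions.
#' Unmatched predictions on a frame without any matched truth make the
#' frame a false positive of the most severe predicted class; a frame with
#' truth boxes but no match is a miss (predicted normal).
#'
#' @param record A [frameRecord()].
#' @param iouThreshold Detection threshold in (0, 1], default 0.5.
#' @return List: trueClass, predClass, detected (any truth matched),
#'   matches (data.frame of matched pairs with IoU).
#' @export
matchFrame <- function(record, iouThreshold = 0.5) {
  if (iouThreshold <= 0 || iouThreshold > 1)
    stop("iouThreshold must lie in (0, 1]")
  truth <- record$truth; pred <- record$pred
  trueClass <- if (nrow(truth)) tissueClasses()[max(.severity(truth$class))] else "normal"
  matches <- data.frame(pred = integer(), truth = integer(), iou = numeric())
  if (nrow(pred) && nrow(truth)) {
    conf <- if ("confidence" %in% names(pred)) pred$confidence else rep(1, nrow(pred))
    usedTruth <- rep(FALSE, nrow(truth))
    # candidate IoUs
    ious <- outer(seq_len(nrow(pred)), seq_len(nrow(truth)),
                  Vectorize(function(i, j) iou(pred[i, ], truth[j, ])))
    for (i in order(-conf, seq_len(nrow(pred)))) {
      cand <- which(!usedTruth & ious[i, ] >= iouThreshold)
      if (!length(cand)) next
      j <- cand[order(-ious[i, cand], cand)][1]
      usedTruth[j] <- TRUE
      matches <- rbind(matches,
                       data.frame(pred = i, truth = j, iou = ious[i, j]))
    }
  }
  detected <- nrow(matches) > 0
  predClass <- if (detected) {
    tissueClasses()[max(.severity(pred$class[matches$pred]))]
  } else if (nrow(pred) && !nrow(truth)) {
    # predictions on a normal frame: false positive of the most severe class
    tissueClasses()[max(.severity(pred$class))]
  } else "normal"
  list(frameId = record$frameId, trueClass = trueClass, predClass = predClass,
       detected = detected, matches = matches)
}

#' Binary detection metrics from frame counts
#'
#' Sensitivity TP/(TP+FN), specificity TN/(TN+FP), precision TP/(TP+FP),
#' F1 (harmonic mean) and accuracy. Zero denominators yield NA
#' ("undefined"), never 0. Values are unit fractions; use
#' [roundPercent()] for integer-percent reporting.
#'
#' @param TP,FN,TN,FP Non-negative integer frame counts.
#' @return Named list of unit-fraction metrics plus the counts.
#' @export
binaryMetrics <- function(TP, FN, TN, FP) {
  counts <- c(TP = unname(TP), FN = unname(FN), TN = unname(TN), FP = unname(FP))
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  total <- sum(counts)
  if (total == 0) stop("at least one frame required")
  safe <- function(num, den) if (den == 0) NA_real_ else num / den
  sens <- safe(TP, TP + FN)
  spec <- safe(TN, TN + FP)
  prec <- safe(TP, TP + FP)
  f1 <- if (is.na(sens) || is.na(prec) || (sens + prec) == 0) NA_real_
        else 2 * sens * prec / (sens + prec)
  list(counts = counts, sensitivity = sens, specificity = spec,
       precision = prec, f1 = f1, accuracy = (TP + TN) / total)
}

#' Round a unit fraction to integer percent (half-up)
#'
#' Reporting convention: percentages to the nearest integer, rounding
#' half-up; applied only at serialization, internals stay full precision.
#'
#' @param x Unit fraction(s) in [0, 1] (NA passed through).
#' @return Integer percent(s).
#' @export
roundPercent <- function(x) ifelse(is.na(x), NA, floor(100 * x + 0.5))

#' @rdname roundPercent
#' @export
roundKappa <- function(x) floor(x * 100 + 0.5) / 100

#' Three-class classification metrics from a confusion matrix
#'
#' Rows are true classes (normal, dysplasia, SCC), columns predictions.
#' Per class: sensitivity = diagonal/row total, precision =
#' diagonal/column total, F1 from those, and two specificity variants:
#' the tabulation variant (fraction of frames of the other classes that
#' were classified into their own correct class, i.e. the sum of the
#' other diagonal entries over the sum of the other row totals) and the
#' standard TN/(TN+FP). Overall accuracy is trace/total.
#'
#' @param cm 3x3 numeric matrix of non-negative counts.
#' @return Named list with per-class metric vectors (unit fractions),
#'   accuracy, and [cohenKappa()].
#' @export
multiclassMetrics <- function(cm) {
  cm <- .checkCM(cm)
  total <- sum(cm)
  rowT <- rowSums(cm); colT <- colSums(cm); diagv <- diag(cm)
  safe <- function(num, den) ifelse(den == 0, NA_real_, num / den)
  sens <- safe(diagv, rowT)
  prec <- safe(diagv, colT)
  f1 <- ifelse(is.na(sens) | is.na(prec) | (sens + prec) == 0,
               NA_real_, 2 * sens * prec / (sens + prec))
  specTab <- vapply(1:3, function(i) {
    oth <- setdiff(1:3, i)
    safe(sum(diagv[oth]), sum(rowT[oth]))
  }, numeric(1))
  specStd <- vapply(1:3, function(i) {
    oth <- setdiff(1:3, i)
    tn <- sum(cm[oth, oth]); fp <- sum(cm[oth, i])
    safe(tn, tn + fp)
  }, numeric(1))
  names(sens) <- names(prec) <- names(f1) <- names(specTab) <-
    names(specStd) <- tissueClasses()
  list(confusion = cm, sensitivity = sens, precision = prec, f1 = f1,
       specificity = specTab, specificityStandard = specStd,
       accuracy = sum(diagv) / total, kappa = cohenKappa(cm))
}

.checkCM <- function(cm) {
  cm <- as.matrix(cm)
  if (!all(dim(cm) == c(3, 3))) stop("confusion matrix must be 3 x 3")
  if (any(cm < 0)) stop("confusion counts must be non-negative")
  dimnames(cm) <- list(true = tissueClasses(), predicted = tissueClasses())
  cm
}

#' Cohen's kappa from a confusion matrix
#'
#' Chance-corrected agreement (p_o - p_e) / (1 - p_e) with the expected
#' agreement p_e computed from the row/column marginals.
#'
#' @param cm Square numeric matrix of counts.
#' @return Kappa in [-1, 1] (NA when p_e = 1).
#' @export
cohenKappa <- function(cm) {
  cm <- as.matrix(cm)
  n <- sum(cm)
  if (n == 0) stop("empty confusion matrix")
  po <- sum(diag(cm)) / n
  pe <- sum(rowSums(cm) * colSums(cm)) / n^2
  if (abs(1 - pe) < 1e-15) return(NA_real_)
  (po - pe) / (1 - pe)
}

#' Evaluate a set of frame records
#'
#' Runs [matchFrame()] on every record and aggregates the outcomes into
#' the binary detection counts (neoplasm vs normal: a neoplasm frame
#' counts as TP when any truth box is matched, the predicted class aside),
#' the 3-class confusion matrix, and the full metrics report. Order of
#' records does not affect the result.
#'
#' @param records List of [frameRecord()] objects with unique frame ids.
#' @param iouThreshold Detection IoU threshold, default 0.5.
#' @return List: binary (counts + [binaryMetrics()]), confusion,
#'   multiclass ([multiclassMetrics()]), outcomes (per-frame data.frame).
#' @export
evaluateDataset <- function(records, iouThreshold = 0.5) {
  if (!length(records)) stop("no frame records supplied")
  ids <- vapply(records, function(r) as.character(r$frameId), character(1))
  if (anyDuplicated(ids)) stop("duplicate frame ids")
  out <- lapply(records, matchFrame, iouThreshold = iouThreshold)
  trueCls <- factor(vapply(out, `[[`, character(1), "trueClass"), tissueClasses())
  predCls <- factor(vapply(out, `[[`, character(1), "predClass"), tissueClasses())
  detected <- vapply(out, `[[`, logical(1), "detected")
  cm <- unclass(table(true = trueCls, predicted = predCls))
  neoplasm <- trueCls != "normal"
  counts <- c(TP = sum(neoplasm & detected),
              FN = sum(neoplasm & !detected),
              TN = sum(!neoplasm & predCls == "normal"),
              FP = sum(!neoplasm & predCls != "normal"))
  list(binary = binaryMetrics(counts["TP"], counts["FN"], counts["TN"], counts["FP"]),
       confusion = .checkCM(cm),
       multiclass = multiclassMetrics(cm),
       outcomes = data.frame(frameId = ids, trueClass = as.character(trueCls),
                             predClass = as.character(predCls),
                             detected = detected))
}

#' Serialize a metrics report
#'
#' Writes the evaluation result as JSON (and optionally a CSV of the
#' rounded per-class table). Percentages are rounded to integers and
#' kappa to two decimals, half-up, only here; the in-memory report stays
#' full precision. Both specificity variants are included.
#'
#' @param evaluation Result of [evaluateDataset()] or [multiclassMetrics()].
#' @param path Output JSON path.
#' @return The path, invisibly.
#' @export
writeMetricsReport <- function(evaluation, path) {
  mc <- if (!is.null(evaluation$multiclass)) evaluation$multiclass else evaluation
  rep <- list(
    confusion = unname(apply(mc$confusion, 1, as.numeric, simplify = FALSE)),
    accuracyPercent = roundPercent(mc$accuracy),
    kappa = roundKappa(mc$kappa),
    perClass = lapply(tissueClasses(), function(cl) list(
      class = cl,
      sensitivityPercent = roundPercent(mc$sensitivity[[cl]]),
      specificityPercent = roundPercent(mc$specificity[[cl]]),
      specificityStandardPercent = roundPercent(mc$specificityStandard[[cl]]),
      precisionPercent = roundPercent(mc$precision[[cl]]),
      f1Percent = roundPercent(mc$f1[[cl]])))
  )
  if (!is.null(evaluation$binary)) {
    b <- evaluation$binary
    rep$detection <- list(counts = as.list(b$counts),
                          sensitivityPercent = roundPercent(b$sensitivity),
                          specificityPercent = roundPercent(b$specificity),
                          precisionPercent = roundPercent(b$precision),
                          f1Percent = roundPercent(b$f1),
                          accuracyPercent = roundPercent(b$accuracy))
  }
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' COCO-style box I/O
#'
#' Reads (or writes) a COCO-style JSON file (images, annotations,
#' categories) into a flat box data.frame with columns frame_id, class,
#' x_min, y_min, x_max, y_max and, for predictions, confidence
#' (from the annotation \code{score} field).
#'
#' @param path JSON path.
#' @return data.frame of boxes.
#' @export
readCOCO <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cats <- obj$categories
  ann <- obj$annotations
  imgs <- obj$images
  if (is.null(ann) || !NROW(ann)) return(emptyBoxes(TRUE))
  bbox <- do.call(rbind, ann$bbox)   # x, y, w, h
  df <- data.frame(
    frame_id = imgs$file_name[match(ann$image_id, imgs$id)],
    class = cats$name[match(ann$category_id, cats$id)],
    x_min = bbox[, 1], y_min = bbox[, 2],
    x_max = bbox[, 1] + bbox[, 3], y_max = bbox[, 2] + bbox[, 4])
  df$confidence <- if (!is.null(ann$score)) ann$score else 1
  df
}

#' @rdname readCOCO
#' @param boxes Flat box data.frame (see [readCOCO()]).
#' @export
writeCOCO <- function(boxes, path) {
  frames <- unique(boxes$frame_id)
  cats <- setdiff(tissueClasses(), "normal")
  obj <- list(
    images = data.frame(id = seq_along(frames), file_name = frames),
    categories = data.frame(id = seq_along(cats), name = cats),
    annotations = data.frame(
      id = seq_len(nrow(boxes)),
      image_id = match(boxes$frame_id, frames),
      category_id = match(boxes$class, cats),
      score = if ("confidence" %in% names(boxes)) boxes$confidence else 1
    )
  )
  obj$annotations$bbox <- lapply(seq_len(nrow(boxes)), function(i)
    c(boxes$x_min[i], boxes$y_min[i],
      boxes$x_max[i] - boxes$x_min[i], boxes$y_max[i] - boxes$y_min[i]))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Flat CSV box I/O
#'
#' CSV dialect: frame_id,class,x_min,y_min,x_max,y_max[,confidence].
#'
#' @param path CSV path.
#' @return data.frame of boxes (read) or path invisibly (write).
#' @export
readBoxCSV <- function(path) utils::read.csv(path, stringsAsFactors = FALSE)

#' @rdname readBoxCSV
#' @param boxes Box data.frame.
#' @export
writeBoxCSV <- function(boxes, path) {
  utils::write.csv(boxes, path, row.names = FALSE)
  invisible(path)
}

#' Assemble frame records from flat box tables
#'
#' @param truthBoxes,predBoxes Flat box data.frames ([readBoxCSV()] /
#'   [readCOCO()] format). Frames present in either table are included;
#'   \code{allFrames} can add truth-empty (normal) frames with no
#'   predictions.
#' @param modality Modality tag for all records.
#' @param allFrames Optional character vector of every frame id.
#' @return List of [frameRecord()] objects.
#' @export
framesFromBoxes <- function(truthBoxes, predBoxes, modality = "WLI",
                            allFrames = NULL) {
  ids <- unique(c(allFrames, truthBoxes$frame_id, predBoxes$frame_id))
  lapply(ids, function(id)
    frameRecord(id,
                truth = truthBoxes[truthBoxes$frame_id == id, , drop = FALSE],
                pred = predBoxes[predBoxes$frame_id == id, , drop = FALSE],
                modality = modality))
}
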