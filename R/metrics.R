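#' Per-pixel confusion counts (film = positive class)
#'
#' Exact pixel tallies between a predicted and a ground-truth mask: TP and
#' FN count film pixels found/missed, FP counts background (soil, straw,
#' clods) misjudged as film, TN the rest.  Counts always sum to the number
#' of evaluated pixels.
#'
#' @param pred,truth [binary_mask()] objects (or `{0, 1}` matrices) of
#'   identical shape.
#' @return An object of class `confusion_counts` with fields `TP`, `TN`,
#'   `FP`, `FN`.
#' @export
confusion <- function(pred, truth) {
  p <- mask_labels(pred)
  t_ <- mask_labels(truth)
  if (!all(dim(p) == dim(t_))) {
    stop_input("prediction (%dx%d) and truth (%dx%d) shapes differ",
               nrow(p), ncol(p), nrow(t_), ncol(t_))
  }
  tp <- sum(p == 1L & t_ == 1L)
  fp <- sum(p == 1L & t_ == 0L)
  fn <- sum(p == 0L & t_ == 1L)
  tn <- length(p) - tp - fp - fn
  structure(list(TP = tp, TN = tn, FP = fp, FN = fn),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion TP=%d TN=%d FP=%d FN=%d>\n", x$TP, x$TN, x$FP, x$FN))
  invisible(x)
}

#' Segmentation metric panel from confusion counts
#'
#' Computes accuracy `(TP+TN)/total`, precision `TP/(TP+FP)`, recall
#' `TP/(TP+FN)`, their harmonic-mean F1, and the two-class mean IoU
#' `0.5 * (TP/(TP+FP+FN) + TN/(TN+FN+FP))` — the average of the film-class
#' and background-class Jaccard indices.  Zero-denominator convention: a
#' ratio whose denominator is 0 is 1 when the corresponding class is absent
#' from both masks with no confusions (vacuously perfect agreement), else 0.
#'
#' @param counts a [confusion()] result.
#' @return An object of class `metric_panel`: list with `accuracy`,
#'   `precision`, `recall`, `f1`, `iou` (and the per-class `iou_film`,
#'   `iou_background`), all in `[0, 1]`.
#' @export
panel <- function(counts) {
  tp <- counts$TP; tn <- counts$TN; fp <- counts$FP; fn <- counts$FN
  total <- tp + tn + fp + fn
  if (total == 0) stop_input("cannot compute metrics over zero pixels")
  accuracy <- (tp + tn) / total
  precision <- if (tp + fp == 0) as.numeric(fn == 0) else tp / (tp + fp)
  recall <- if (tp + fn == 0) as.numeric(fp == 0) else tp / (tp + fn)
  f1 <- if (precision + recall == 0) 0 else 2 * precision * recall / (precision + recall)
  iou_film <- if (tp + fp + fn == 0) 1 else tp / (tp + fp + fn)
  iou_bg <- if (tn + fn + fp == 0) 1 else tn / (tn + fn + fp)
  structure(
    list(accuracy = accuracy, precision = precision, recall = recall,
         f1 = f1, iou = (iou_film + iou_bg) / 2,
         iou_film = iou_film, iou_background = iou_bg),
    class = "metric_panel"
  )
}

#' @export
print.metric_panel <- function(x, ...) {
  cat(sprintf(
    "<metric_panel acc=%.2f%% prec=%.2f%% rec=%.2f%% F1=%.2f%% IoU=%.2f%%>\n",
    100 * x$accuracy, 100 * x$precision, 100 * x$recall, 100 * x$f1,
    100 * x$iou))
  invisible(x)
}

#' Mean IoU over a set of mask pairs
#'
#' Two aggregation readings of "mean IoU over a test set":
#' `per_image_mean` (default) averages the two-class IoU computed per image;
#' `pooled` sums the confusion counts over all images first and applies the
#' two-class IoU once.
#'
#' @param pairs non-empty list; each element a list with `pred` and `truth`
#'   masks.
#' @param mode `"per_image_mean"` or `"pooled"`.
#' @return The mean IoU in `[0, 1]`.
#' @export
miou_over_set <- function(pairs, mode = c("per_image_mean", "pooled")) {
  mode <- match.arg(mode)
  if (length(pairs) == 0) stop_input("empty pair list")
  counts <- lapply(pairs, function(p) confusion(p$pred, p$truth))
  if (mode == "per_image_mean") {
    mean(vapply(counts, function(ct) panel(ct)$iou, numeric(1)))
  } else {
    pooled <- structure(
      list(TP = sum(vapply(counts, `[[`, numeric(1), "TP")),
           TN = sum(vapply(counts, `[[`, numeric(1), "TN")),
           FP = sum(vapply(counts, `[[`, numeric(1), "FP")),
           FN = sum(vapply(counts, `[[`, numeric(1), "FN"))),
      class = "confusion_counts")
    panel(pooled)$iou
  }
}
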