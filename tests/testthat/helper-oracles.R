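# Brute-force double-loop oracles, independent of the package's vectorized
# implementations.

oracle_confusion <- function(pred, truth) {
  tp <- tn <- fp <- fn <- 0L
  for (i in seq_len(nrow(pred))) {
    for (j in seq_len(ncol(pred))) {
      p <- pred[i, j]; t_ <- truth[i, j]
      if (p == 1 && t_ == 1) tp <- tp + 1L
      else if (p == 0 && t_ == 0) tn <- tn + 1L
      else if (p == 1 && t_ == 0) fp <- fp + 1L
      else fn <- fn + 1L
    }
  }
  list(TP = tp, TN = tn, FP = fp, FN = fn)
}

oracle_panel <- function(ct) {
  total <- ct$TP + ct$TN + ct$FP + ct$FN
  pr <- if (ct$TP + ct$FP == 0) as.numeric(ct$FN == 0) else ct$TP / (ct$TP + ct$FP)
  rc <- if (ct$TP + ct$FN == 0) as.numeric(ct$FP == 0) else ct$TP / (ct$TP + ct$FN)
  list(
    accuracy = (ct$TP + ct$TN) / total, precision = pr, recall = rc,
    f1 = if (pr + rc == 0) 0 else 2 * pr * rc / (pr + rc),
    iou = 0.5 *
      ((if (ct$TP + ct$FP + ct$FN == 0) 1 else ct$TP / (ct$TP + ct$FP + ct$FN)) +
         (if (ct$TN + ct$FN + ct$FP == 0) 1 else ct$TN / (ct$TN + ct$FN + ct$FP)))
  )
}
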