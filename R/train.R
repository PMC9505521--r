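#' Training configuration
#'
#' Per-pixel categorical cross-entropy on integer labels, the Adam
#' optimizer with initial learning rate 0.001, batch size 6 and 55 epochs by
#' default; only the best model (by validation loss, or optionally
#' validation accuracy) is kept.
#'
#' @param learning_rate positive Adam learning rate.
#' @param batch_size training batch size (>= 1); gradients are averaged over
#'   the batch.
#' @param epochs number of training epochs (>= 1); no early stopping.
#' @param checkpoint_metric `"val_loss"` (minimized, default) or
#'   `"val_accuracy"` (maximized).
#' @param seed seed for weight initialization order and shuffling.
#' @return An object of class `train_config`.
#' @export
train_config <- function(learning_rate = 0.001, batch_size = 6L,
                         epochs = 55L,
                         checkpoint_metric = c("val_loss", "val_accuracy"),
                         seed = 1L) {
  if (learning_rate < 0) stop_input("learning_rate must be >= 0")
  if (batch_size < 1) stop_input("batch_size must be >= 1")
  if (epochs < 1) stop_input("epochs must be >= 1")
  structure(
    list(learning_rate = learning_rate, batch_size = as.integer(batch_size),
         epochs = as.integer(epochs),
         checkpoint_metric = match.arg(checkpoint_metric),
         seed = as.integer(seed)),
    class = "train_config"
  )
}

eval_loss_acc <- function(model, pairs) {
  losses <- numeric(length(pairs)); accs <- numeric(length(pairs))
  for (i in seq_along(pairs)) {
    p <- pairs[[i]]
    x <- image_pixels(p$image) / 255
    fw <- unet_forward(model, x)
    sc <- softmax_ce(fw$logits, mask_labels(p$mask))
    losses[i] <- sc$loss; accs[i] <- sc$accuracy
  }
  c(loss = mean(losses), accuracy = mean(accs))
}

#' Train the segmentation network
#'
#' Runs the configured number of epochs over an [epoch_stream()] (one fresh
#' augmented variant of each training pair per epoch), accumulating
#' per-pixel cross-entropy gradients over batches and stepping Adam.
#' Validation pairs are evaluated untouched (no augmentation, full
#' resolution) after every epoch; weights are persisted to the checkpoint
#' only when the checkpoint metric improves.  Training aborts with a
#' diagnostic naming the epoch if the loss becomes non-finite.
#'
#' @param model a [build_modified_unet()] network (initial weights).
#' @param train_pairs,val_pairs non-empty lists of pairs (lists with
#'   `image`, `mask`).
#' @param aug_cfg an [augment_config()].
#' @param cfg a [train_config()].
#' @param checkpoint_path where the best weights are written.
#' @param verbose print one log line per epoch.
#' @return An object of class `unet_fit`: list with `model` (best weights),
#'   `history` (one row per epoch: train/validation loss and pixel
#'   accuracy), `best_epoch`, `checkpoint_path`, and the configs used.
#' @export
train_model <- function(model, train_pairs, val_pairs, aug_cfg,
                        cfg = train_config(),
                        checkpoint_path = tempfile(fileext = ".rds"),
                        verbose = FALSE) {
  if (length(train_pairs) == 0) stop_input("empty training set")
  if (length(val_pairs) == 0) stop_input("empty validation set")

  stream <- epoch_stream(train_pairs, aug_cfg, cfg$epochs)
  state <- adam_init(model$params)
  n_train <- length(train_pairs)
  history <- vector("list", cfg$epochs)
  best_val <- Inf * if (cfg$checkpoint_metric == "val_loss") 1 else -1
  best_epoch <- NA_integer_
  better <- if (cfg$checkpoint_metric == "val_loss") {
    function(new, old) new < old
  } else {
    function(new, old) new > old
  }

  for (epoch in seq_len(cfg$epochs)) {
    ep_loss <- 0; ep_acc <- 0
    done <- 0L
    while (done < n_train) {
      nb <- min(cfg$batch_size, n_train - done)
      gacc <- NULL
      for (b in seq_len(nb)) {
        p <- stream$next_pair()
        x <- image_pixels(p$image) / 255
        fw <- unet_forward(model, x, keep_cache = TRUE)
        sc <- softmax_ce(fw$logits, mask_labels(p$mask))
        ep_loss <- ep_loss + sc$loss; ep_acc <- ep_acc + sc$accuracy
        gacc <- accumulate_grads(gacc, unet_backward(model, fw$cache, sc$glogits))
      }
      gacc <- scale_grads(gacc, 1 / nb)
      st <- adam_step(model$params, gacc, state, cfg$learning_rate)
      model$params <- st$params
      state <- st$state
      done <- done + nb
    }
    train_loss <- ep_loss / n_train
    train_acc <- ep_acc / n_train
    if (!is.finite(train_loss)) {
      stop_input("training diverged at epoch %d: non-finite loss", epoch)
    }
    val <- eval_loss_acc(model, val_pairs)
    metric <- if (cfg$checkpoint_metric == "val_loss") val["loss"] else val["accuracy"]
    improved <- better(metric, best_val)
    if (improved) {
      best_val <- metric
      best_epoch <- epoch
      save_checkpoint(model, checkpoint_path)
    }
    history[[epoch]] <- data.frame(
      epoch = epoch, train_loss = train_loss, train_accuracy = train_acc,
      val_loss = unname(val["loss"]), val_accuracy = unname(val["accuracy"]),
      checkpointed = improved)
    if (verbose) {
      message(sprintf(
        "epoch %3d | loss %.4f acc %.4f | val_loss %.4f val_acc %.4f%s",
        epoch, train_loss, train_acc, val["loss"], val["accuracy"],
        if (improved) " *" else ""))
    }
  }
  history <- do.call(rbind, history)
  structure(
    list(model = load_checkpoint(checkpoint_path), history = history,
         best_epoch = best_epoch, checkpoint_path = checkpoint_path,
         train_config = cfg, augment_config = aug_cfg,
         samples_streamed = stream$yielded()),
    class = "unet_fit"
  )
}

#' Evaluate a model on labelled pairs, optionally stratified
#'
#' Predicts a mask for every pair and reports the full metric panel overall
#' and per metadata group (weather condition or flight height), mirroring
#' stratified test-set evaluation.  Metric columns are in percent.
#'
#' @param object a `unet_fit` or `modified_unet`; alternatively supply
#'   `predictions` directly (e.g. ground truth for an oracle check).
#' @param pairs list of pairs with `image`, `mask`, and metadata fields when
#'   `group_by` is used.
#' @param group_by optional metadata key: `"weather"` or `"height_m"`.
#' @param predictions optional list of predicted masks overriding the model.
#' @param csv_path optional path; the table is written as CSV with 2-decimal
#'   percent values.
#' @return A data.frame with one overall row plus one row per group:
#'   `group`, `n_images`, `accuracy`, `precision`, `recall`, `f1`,
#'   `miou_per_image_mean`, `miou_pooled` (percent).
#' @export
evaluate_model <- function(object, pairs, group_by = NULL, predictions = NULL,
                           csv_path = NULL) {
  if (length(pairs) == 0) stop_input("no pairs to evaluate")
  if (!is.null(group_by) && !group_by %in% c("weather", "height_m")) {
    stop_input("unknown group_by key '%s' (use 'weather' or 'height_m')", group_by)
  }
  if (is.null(predictions)) {
    predictions <- lapply(pairs, function(p) predict_mask(object, p$image))
  }
  counts <- lapply(seq_along(pairs), function(i) {
    confusion(predictions[[i]], pairs[[i]]$mask)
  })
  row_for <- function(label, idx) {
    cts <- counts[idx]
    pooled <- structure(
      list(TP = sum(vapply(cts, `[[`, numeric(1), "TP")),
           TN = sum(vapply(cts, `[[`, numeric(1), "TN")),
           FP = sum(vapply(cts, `[[`, numeric(1), "FP")),
           FN = sum(vapply(cts, `[[`, numeric(1), "FN"))),
      class = "confusion_counts")
    pp <- panel(pooled)
    per_img_iou <- vapply(cts, function(ct) panel(ct)$iou, numeric(1))
    data.frame(group = label, n_images = length(idx),
               accuracy = 100 * pp$accuracy, precision = 100 * pp$precision,
               recall = 100 * pp$recall, f1 = 100 * pp$f1,
               miou_per_image_mean = 100 * mean(per_img_iou),
               miou_pooled = 100 * pp$iou, stringsAsFactors = FALSE)
  }
  out <- row_for("overall", seq_along(pairs))
  if (!is.null(group_by)) {
    vals <- vapply(pairs, function(p) {
      v <- p[[group_by]]
      if (is.null(v)) stop_input("pairs carry no '%s' metadata", group_by)
      as.character(v)
    }, character(1))
    for (lev in sort(unique(vals))) {
      out <- rbind(out, row_for(paste0(group_by, "=", lev), which(vals == lev)))
    }
  }
  if (!is.null(csv_path)) {
    fmt <- out
    num <- vapply(fmt, is.numeric, logical(1)) & names(fmt) != "n_images"
    fmt[num] <- lapply(fmt[num], function(x) sprintf("%.2f", x))
    write.csv(fmt, csv_path, row.names = FALSE, quote = FALSE)
  }
  out
}

# ---- unet_fit methods ------------------------------------------------------

#' @export
print.unet_fit <- function(x, ...) {
  cat(sprintf(
    "<unet_fit %d epoch(s), best epoch %d (%s %.4f), %s parameters>\n",
    nrow(x$history), x$best_epoch, x$train_config$checkpoint_metric,
    if (x$train_config$checkpoint_metric == "val_loss") {
      x$history$val_loss[x$best_epoch]
    } else {
      x$history$val_accuracy[x$best_epoch]
    },
    format(count_params(x), big.mark = ",")))
  invisible(x)
}

#' @export
summary.unet_fit <- function(object, ...) {
  cat("Training history:\n")
  print(object$history, row.names = FALSE)
  cat(sprintf("\nBest epoch: %d | augmented samples streamed: %d\n",
              object$best_epoch, object$samples_streamed))
  invisible(object)
}

#' @export
plot.unet_fit <- function(x, ...) {
  h <- x$history
  old <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(old))
  graphics::plot(h$epoch, h$train_loss, type = "l", xlab = "epoch",
                 ylab = "loss", main = "Loss",
                 ylim = range(c(h$train_loss, h$val_loss)))
  graphics::lines(h$epoch, h$val_loss, lty = 2, col = 2)
  graphics::legend("topright", c("train", "validation"), lty = 1:2,
                   col = 1:2, bty = "n")
  graphics::plot(h$epoch, h$train_accuracy, type = "l", xlab = "epoch",
                 ylab = "pixel accuracy", main = "Accuracy",
                 ylim = range(c(h$train_accuracy, h$val_accuracy)))
  graphics::lines(h$epoch, h$val_accuracy, lty = 2, col = 2)
  invisible(x)
}

#' @export
predict.unet_fit <- function(object, newdata, type = c("mask", "prob"), ...) {
  type <- match.arg(type)
  one <- function(img) {
    if (type == "mask") predict_mask(object, img) else predict_probs(object, img)
  }
  if (inherits(newdata, "field_image") || is.array(newdata)) return(one(newdata))
  lapply(newdata, function(p) one(if (is.list(p) && !is.null(p$image)) p$image else p))
}
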