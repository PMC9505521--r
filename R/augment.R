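#' Training augmentation configuration
#'
#' The four per-epoch stochastic augmentations applied to each training
#' pair: one random crop, independent left-right and up-down flips, and a
#' multiplicative brightness adjustment (image only; masks carry labels, not
#' radiometry).  Defaults follow the working resolution of 1200 x 600 with
#' 1024 x 512 crops.
#'
#' @param crop_width,crop_height crop size in pixels (must fit inside the
#'   working resolution).
#' @param p_flip_lr,p_flip_ud flip probabilities in `[0, 1]`.
#' @param brightness_factor_range ordered positive pair; a scalar factor is
#'   drawn uniformly per call and applied with clipping to `[0, 255]`.
#' @param seed stream seed.
#' @return An object of class `augment_config`.
#' @export
augment_config <- function(crop_width = 1024L, crop_height = 512L,
                           p_flip_lr = 0.5, p_flip_ud = 0.5,
                           brightness_factor_range = c(0.8, 1.2),
                           seed = 1L) {
  if (crop_width < 1 || crop_height < 1) stop_input("crop size must be positive")
  if (p_flip_lr < 0 || p_flip_lr > 1 || p_flip_ud < 0 || p_flip_ud > 1) {
    stop_input("flip probabilities must lie in [0, 1]")
  }
  if (length(brightness_factor_range) != 2 ||
      any(brightness_factor_range <= 0) ||
      brightness_factor_range[1] > brightness_factor_range[2]) {
    stop_input("brightness_factor_range must be an ordered positive pair")
  }
  structure(
    list(crop_width = as.integer(crop_width),
         crop_height = as.integer(crop_height),
         p_flip_lr = p_flip_lr, p_flip_ud = p_flip_ud,
         brightness_factor_range = brightness_factor_range,
         seed = as.integer(seed)),
    class = "augment_config"
  )
}

#' Augment one image/mask pair
#'
#' Applies, in order: a uniformly positioned crop of
#' `crop_height x crop_width`; a left-right flip with probability
#' `p_flip_lr`; an up-down flip with probability `p_flip_ud` (geometric
#' transforms applied identically to image and mask); and a multiplicative
#' brightness factor drawn uniformly from `brightness_factor_range`, applied
#' to the image channels with clipping to `[0, 255]`.  The mask is never
#' touched by brightness.
#'
#' @param image a [field_image()].
#' @param mask the paired [binary_mask()].
#' @param cfg an [augment_config()].
#' @param seed per-call seed (defaults to `cfg$seed`).
#' @return A list with augmented `image` and `mask`.
#' @export
augment_pair <- function(image, mask, cfg, seed = NULL) {
  pix <- image_pixels(image)
  lab <- mask_labels(mask)
  H <- dim(pix)[1]; W <- dim(pix)[2]
  ch <- cfg$crop_height; cw <- cfg$crop_width
  if (H < ch || W < cw) {
    stop_input("image (%dx%d) is smaller than the crop size (%dx%d)",
               W, H, cw, ch)
  }
  with_seed(seed %||% cfg$seed, {
    i0 <- sample.int(H - ch + 1L, 1)
    j0 <- sample.int(W - cw + 1L, 1)
    pix <- pix[i0:(i0 + ch - 1L), j0:(j0 + cw - 1L), , drop = FALSE]
    lab <- lab[i0:(i0 + ch - 1L), j0:(j0 + cw - 1L), drop = FALSE]
    if (runif(1) < cfg$p_flip_lr) {
      pix <- pix[, cw:1, , drop = FALSE]
      lab <- lab[, cw:1, drop = FALSE]
    }
    if (runif(1) < cfg$p_flip_ud) {
      pix <- pix[ch:1, , , drop = FALSE]
      lab <- lab[ch:1, , drop = FALSE]
    }
    f <- runif(1, cfg$brightness_factor_range[1], cfg$brightness_factor_range[2])
    pix <- clip255(round(pix * f))
  })
  list(image = field_image(pix, weather = image$weather,
                           height_m = image$height_m,
                           source_id = image$source_id),
       mask = binary_mask(lab))
}

#' Stream one augmented variant of every training pair per epoch
#'
#' Returns an iterator that, over `epochs` passes, yields exactly one
#' freshly augmented variant of each training pair per epoch — so 480
#' training pairs streamed for 55 epochs produce exactly 26,400 augmented
#' samples.  The yield counter is exposed for audit.  Augmentation seeds are
#' derived deterministically from `cfg$seed` and the yield index, so a
#' stream is reproducible end to end.
#'
#' @param train_pairs non-empty list of pairs (lists with `image`, `mask`).
#' @param cfg an [augment_config()].
#' @param epochs number of passes (>= 1).
#' @return An object of class `epoch_stream`: list with `next_pair()`
#'   (returns the next augmented pair, or `NULL` when exhausted),
#'   `yielded()` (samples yielded so far), and `total`.
#' @export
epoch_stream <- function(train_pairs, cfg, epochs) {
  if (length(train_pairs) == 0) stop_input("empty training list")
  if (epochs < 1) stop_input("epochs must be >= 1")
  n <- length(train_pairs)
  total <- n * as.integer(epochs)
  i <- 0L
  next_pair <- function() {
    if (i >= total) return(NULL)
    i <<- i + 1L
    p <- train_pairs[[((i - 1L) %% n) + 1L]]
    out <- augment_pair(p$image, p$mask, cfg, seed = derive_seed(cfg$seed, i))
    out$epoch <- ((i - 1L) %/% n) + 1L
    out
  }
  structure(
    list(next_pair = next_pair, yielded = function() i, total = total,
         n_pairs = n, epochs = as.integer(epochs)),
    class = "epoch_stream"
  )
}
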