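#' Model configuration for the slimmed inception U-Net
#'
#' Architecture hyper-parameters of the segmentation network: three
#' down-sampling stages (so both 1200 x 600 and 1024 x 512 working sizes
#' divide evenly; a fourth pooling would not divide 600), each an inception
#' block followed by 2 x 2 max-pooling; an inception bottleneck; a mirrored
#' decoder of 2 x 2 transposed convolutions with skip concatenation and a
#' single 3 x 3 convolution per stage; and a 1 x 1 two-class head.  The
#' default widths (64, 128, 256; bottleneck 448; branch = out/2) were tuned
#' by exact parameter count to a budget of about 3.14 million trainable
#' parameters, roughly a tenth of a classic U-Net.
#'
#' @param encoder_channels output channels of the encoder stages.
#' @param bottleneck_channels bottleneck output channels.
#' @param n_classes number of output classes (2: film/background).
#' @param input_channels input channels (3 for RGB).
#' @param n_downsamplings number of pooling stages; inputs must be divisible
#'   by `2^n_downsamplings`.
#' @return An object of class `model_config`.
#' @export
model_config <- function(encoder_channels = c(64L, 128L, 256L),
                         bottleneck_channels = 448L, n_classes = 2L,
                         input_channels = 3L, n_downsamplings = 3L) {
  if (length(encoder_channels) != n_downsamplings) {
    stop_input("need one encoder width per down-sampling stage")
  }
  if (any(c(encoder_channels, bottleneck_channels, n_classes,
            input_channels) <= 0)) {
    stop_input("channel counts must be positive")
  }
  structure(
    list(encoder_channels = as.integer(encoder_channels),
         bottleneck_channels = as.integer(bottleneck_channels),
         n_classes = as.integer(n_classes),
         input_channels = as.integer(input_channels),
         n_downsamplings = as.integer(n_downsamplings)),
    class = "model_config"
  )
}

#' Specification of one inception down-sampling block
#'
#' The block replaces a plain 3 x 3 convolution with two parallel branches —
#' a 1 x 1 convolution, and a 1 x 1 followed by a 3 x 3 convolution (each to
#' `branch_channels`) — whose outputs are channel-concatenated and reduced
#' by a trailing 1 x 1 convolution to `out_channels`.  All convolutions use
#' same-padding and ReLU, so spatial size is preserved while features of
#' several receptive-field scales are fused.
#'
#' @param in_channels,branch_channels,out_channels positive channel counts.
#' @return An object of class `inception_spec`.
#' @export
inception_spec <- function(in_channels, branch_channels, out_channels) {
  if (any(c(in_channels, branch_channels, out_channels) <= 0)) {
    stop_input("inception block channel counts must be positive")
  }
  structure(list(in_channels = as.integer(in_channels),
                 branch_channels = as.integer(branch_channels),
                 out_channels = as.integer(out_channels)),
            class = "inception_spec")
}

#' Build a standalone inception block
#'
#' @param spec an [inception_spec()].
#' @param seed initialization seed (He-normal weights, zero biases).
#' @return An object of class `inception_block` holding the parameters.
#' @export
build_inception_block <- function(spec, seed = 1L) {
  params <- with_seed(seed, init_inception_params(
    spec$in_channels, spec$branch_channels, spec$out_channels))
  structure(list(spec = spec, params = params), class = "inception_block")
}

#' Forward an input through an inception block
#'
#' @param block an [build_inception_block()] result.
#' @param x an `(H, W, in_channels)` numeric array.
#' @return An `(H, W, out_channels)` array; spatial size is preserved.
#' @export
inception_forward <- function(block, x) {
  incep_fwd(x, block$params)$out
}

#' Closed-form parameter count of one inception block
#'
#' Weights plus biases of the four convolutions: the two 1 x 1 input
#' branches, the 3 x 3 branch tail, and the trailing 1 x 1 reduction from
#' the concatenated `2 * branch` channels to `out`.
#'
#' @param in_channels,branch_channels,out_channels channel counts.
#' @return Integer parameter count.
#' @export
inception_param_count <- function(in_channels, branch_channels, out_channels) {
  cin <- in_channels; b <- branch_channels; cout <- out_channels
  (cin * b + b) + (cin * b + b) + (9 * b * b + b) + (2 * b * cout + cout)
}

#' Build the slimmed inception U-Net
#'
#' @param cfg a [model_config()].
#' @param seed weight-initialization seed.
#' @return An object of class `modified_unet`: list with `config` and the
#'   parameter arrays.
#' @export
build_modified_unet <- function(cfg = model_config(), seed = 1L) {
  nd <- cfg$n_downsamplings
  ec <- cfg$encoder_channels
  with_seed(seed, {
    params <- list()
    cin <- cfg$input_channels
    for (k in seq_len(nd)) {
      params[[paste0("enc", k)]] <-
        init_inception_params(cin, max(1L, ec[k] %/% 2L), ec[k])
      cin <- ec[k]
    }
    params$bott <- init_inception_params(
      cin, max(1L, cfg$bottleneck_channels %/% 2L), cfg$bottleneck_channels)
    cin <- cfg$bottleneck_channels
    for (k in rev(seq_len(nd))) {
      params[[paste0("dec", k)]] <- list(
        upw = init_conv(2, 2, cin, ec[k]), upb = numeric(ec[k]),
        convw = init_conv(3, 3, 2L * ec[k], ec[k]), convb = numeric(ec[k]))
      cin <- ec[k]
    }
    params$head <- list(w = init_conv(1, 1, ec[1], cfg$n_classes),
                        b = numeric(cfg$n_classes))
    structure(list(config = cfg, params = params), class = "modified_unet")
  })
}

#' Count trainable parameters
#'
#' @param object a `modified_unet`, `inception_block`, `unet_fit`, or a raw
#'   parameter list.
#' @return Total number of trainable scalars.
#' @export
count_params <- function(object) {
  params <- if (inherits(object, "unet_fit")) {
    object$model$params
  } else if (!is.null(object$params)) {
    object$params
  } else {
    object
  }
  sum(vapply(params, function(stage) {
    sum(vapply(stage, length, numeric(1)))
  }, numeric(1)))
}

#' Parameter count of a reference classic U-Net
#'
#' Closed-form count for the original U-shaped baseline: `depth` poolings,
#' base width doubling per level, two 3 x 3 convolutions per encoder/decoder
#' stage and bottleneck, 2 x 2 transposed-convolution upsampling, and a
#' 1 x 1 head.  With the defaults (depth 4, base 64) this is about
#' 31 million parameters — the yardstick against which the slimmed model's
#' roughly tenfold reduction is measured.
#'
#' @param base_width channels of the first stage.
#' @param depth number of poolings.
#' @param in_channels,n_classes input/output channels.
#' @return Total parameter count.
#' @export
classic_unet_param_count <- function(base_width = 64L, depth = 4L,
                                     in_channels = 3L, n_classes = 2L) {
  count <- 0
  cin <- in_channels
  for (i in seq_len(depth + 1L)) {       # encoder stages + bottleneck
    ch <- base_width * 2^(i - 1L)
    count <- count + (9 * cin * ch + ch) + (9 * ch * ch + ch)
    cin <- ch
  }
  for (i in rev(seq_len(depth))) {       # decoder stages
    ch <- base_width * 2^(i - 1L)
    count <- count + (4 * cin * ch + ch)                    # 2x2 up-conv
    count <- count + (9 * (2 * ch) * ch + ch) + (9 * ch * ch + ch)
    cin <- ch
  }
  count + cin * n_classes + n_classes
}

#' Per-pixel class probabilities for an image
#'
#' Runs the forward pass and softmax head.  The input is normalized to
#' `[0, 1]`; its sides must be divisible by `2^n_downsamplings` (use
#' [predict_mask()] for automatic reflect-padding).
#'
#' @param object a `modified_unet` or `unet_fit`.
#' @param image a [field_image()] or `(H, W, 3)` array in `[0, 255]`.
#' @return An `(H, W, 2)` array of class probabilities summing to 1 per
#'   pixel (class 1 = background, class 2 = film).
#' @export
predict_probs <- function(object, image) {
  model <- resolve_model(object)
  x <- image_pixels(image) / 255
  softmax_probs(unet_forward(model, x)$logits)
}

#' Predict a binary film mask for an image
#'
#' Argmax decoding of the two-class head with ties broken toward background,
#' so an uninformative half/half output never hallucinates film.  Inputs
#' whose sides are not divisible by `2^n_downsamplings` are reflect-padded
#' on the bottom/right and the output cropped back, so the mask always has
#' the input's shape.
#'
#' @param object a `modified_unet` or `unet_fit`.
#' @param image a [field_image()] or `(H, W, 3)` array in `[0, 255]`.
#' @return A [binary_mask()] of the input's height and width.
#' @export
predict_mask <- function(object, image) {
  model <- resolve_model(object)
  x <- image_pixels(image)
  if (dim(x)[3] != model$config$input_channels) {
    stop_input("expected %d input channels, got %d",
               model$config$input_channels, dim(x)[3])
  }
  H <- dim(x)[1]; W <- dim(x)[2]
  mult <- 2^model$config$n_downsamplings
  Hp <- ceiling(H / mult) * mult
  Wp <- ceiling(W / mult) * mult
  if (Hp != H || Wp != W) {
    if (Hp - H >= H || Wp - W >= W) {
      stop_input("image too small to reflect-pad to a multiple of %d", mult)
    }
    ridx <- c(seq_len(H), H - seq_len(Hp - H))
    cidx <- c(seq_len(W), W - seq_len(Wp - W))
    x <- x[ridx, cidx, , drop = FALSE]
  }
  probs <- softmax_probs(unet_forward(model, x / 255)$logits)
  probs <- probs[seq_len(H), seq_len(W), , drop = FALSE]
  binary_mask(matrix(as.integer(probs[, , 2] > probs[, , 1]), H, W))
}

resolve_model <- function(object) {
  if (inherits(object, "unet_fit")) return(object$model)
  if (inherits(object, "modified_unet")) return(object)
  stop_input("expected a modified_unet or unet_fit object")
}

#' @export
print.modified_unet <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<modified_unet enc=[%s] bottleneck=%d, %d down-samplings, %s parameters>\n",
    paste(cfg$encoder_channels, collapse = ", "), cfg$bottleneck_channels,
    cfg$n_downsamplings, format(count_params(x), big.mark = ",")))
  invisible(x)
}

#' Save / load a model checkpoint
#'
#' Single-file serialization of the parameter arrays together with the
#' `model_config`, so a checkpoint round-trips bit-exactly.
#'
#' @param model a `modified_unet` (or `unet_fit`, whose best model is saved).
#' @param path checkpoint file path.
#' @return `save_checkpoint` the path, invisibly; `load_checkpoint` the
#'   restored `modified_unet`.
#' @export
save_checkpoint <- function(model, path) {
  model <- resolve_model(model)
  saveRDS(list(config = model$config, params = model$params), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  structure(list(config = obj$config, params = obj$params),
            class = "modified_unet")
}
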