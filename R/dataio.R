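#' Load an image/mask pair from PNG files
#'
#' The image must be 8-bit RGB; the mask a single-channel PNG whose pixel
#' values are exactly two-level (`{0, 255}` on disk, or already `{0, 1}`),
#' normalized in memory to `{0, 1}` with film = 1.  A mask containing any
#' other value, or whose shape does not match the image, is a format error.
#'
#' @param image_path,mask_path paths to the PNG files.
#' @param weather,height_m,source_id optional metadata attached to the image.
#' @return A list with elements `image` ([field_image()]) and `mask`
#'   ([binary_mask()]).
#' @export
load_pair <- function(image_path, mask_path, weather = "unknown",
                      height_m = NA_real_, source_id = basename(image_path)) {
  if (!file.exists(image_path)) stop_input("cannot read image '%s'", image_path)
  if (!file.exists(mask_path)) stop_input("cannot read mask '%s'", mask_path)
  a <- png::readPNG(image_path)
  if (length(dim(a)) != 3L || dim(a)[3] < 3L) {
    stop_input("image '%s' is not RGB", image_path)
  }
  pix <- round(a[, , 1:3, drop = FALSE] * 255)

  m <- png::readPNG(mask_path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  vals <- round(m * 255)
  uv <- sort(unique(as.vector(vals)))
  ok <- all(uv %in% c(0, 255)) || all(uv %in% c(0, 1))
  if (!ok) {
    stop_input("mask '%s' contains values other than the two allowed levels: %s",
               mask_path, paste(utils::head(setdiff(uv, c(0, 1, 255)), 8),
                                collapse = ", "))
  }
  labels <- matrix(as.integer(vals > 0), nrow(vals), ncol(vals))
  if (!all(dim(labels) == dim(pix)[1:2])) {
    stop_input("image (%dx%d) and mask (%dx%d) shapes differ",
               dim(pix)[1], dim(pix)[2], nrow(labels), ncol(labels))
  }
  list(image = field_image(pix, weather = weather, height_m = height_m,
                           source_id = source_id),
       mask = binary_mask(labels))
}

#' Save an image/mask pair as PNG files
#'
#' Images are written as 8-bit RGB, masks as single-channel PNGs with the
#' in-memory `{0, 1}` labels mapped to `{0, 255}` on disk.
#'
#' @param image a [field_image()] (or H x W x 3 array in `[0, 255]`).
#' @param mask a [binary_mask()] (or `{0, 1}` matrix).
#' @param image_path,mask_path destination paths.
#' @export
save_pair <- function(image, mask, image_path, mask_path) {
  png::writePNG(image_pixels(image) / 255, image_path)
  png::writePNG(mask_labels(mask) * 1.0, mask_path)
  invisible(c(image_path, mask_path))
}

#' Resize an image/mask pair to the working resolution
#'
#' The image is resampled bilinearly, the mask with nearest-neighbour so
#' labels remain binary; a bilinear mask resample would fabricate
#' intermediate label values.  Default target is the 1200 (wide) x 600
#' (high) working resolution; sizes are quoted width x height while arrays
#' are (rows = height, cols = width).
#'
#' @param image a [field_image()].
#' @param mask a [binary_mask()].
#' @param out_width,out_height target size in pixels.
#' @return A list with resized `image` and `mask`.
#' @export
resize_pair <- function(image, mask, out_width = 1200L, out_height = 600L) {
  if (out_width < 1 || out_height < 1) {
    stop_input("output dimensions must be positive")
  }
  pix <- image_pixels(image)
  lab <- mask_labels(mask)
  if (nrow(lab) == out_height && ncol(lab) == out_width &&
      dim(pix)[1] == out_height && dim(pix)[2] == out_width) {
    return(list(image = image, mask = mask))
  }
  # EBImage stores the x (width) axis first, hence the transposes
  ei <- EBImage::Image(aperm(pix, c(2, 1, 3)) / 255, colormode = "Color")
  ri <- EBImage::resize(ei, w = out_width, h = out_height, filter = "bilinear")
  newpix <- round(clip255(aperm(EBImage::imageData(ri), c(2, 1, 3)) * 255))

  em <- EBImage::Image(t(lab))
  rm_ <- EBImage::resize(em, w = out_width, h = out_height, filter = "none")
  newlab <- t(EBImage::imageData(rm_))

  list(image = field_image(newpix, weather = image$weather,
                           height_m = image$height_m,
                           source_id = image$source_id),
       mask = binary_mask(newlab))
}

#' Partition dataset identifiers into train/validation/test
#'
#' Deterministic seeded shuffle followed by a rounded partition: the
#' validation and test sizes are `round(n * ratio)` and the remainder goes
#' to train, so 600 ids yield 480/60/60 and 10 ids yield 8/1/1.
#'
#' @param ids vector of identifiers.
#' @param ratios train/validation/test proportions summing to 1.
#' @param seed shuffle seed.
#' @return An object of class `dataset_split`: list with disjoint `train`,
#'   `validation`, `test` whose union is `ids`.
#' @export
split_dataset <- function(ids, ratios = c(0.8, 0.1, 0.1), seed = 1L) {
  n <- length(ids)
  if (n == 0) stop_input("cannot split an empty id list")
  if (abs(sum(ratios) - 1) > 1e-8) stop_input("split ratios must sum to 1")
  ord <- with_seed(seed, sample.int(n))
  n_val <- round(n * ratios[2])
  n_test <- round(n * ratios[3])
  n_train <- n - n_val - n_test
  if (n_train < 0) stop_input("split ratios leave no training items")
  structure(
    list(train = ids[ord[seq_len(n_train)]],
         validation = ids[ord[n_train + seq_len(n_val)]],
         test = ids[ord[n_train + n_val + seq_len(n_test)]]),
    class = "dataset_split"
  )
}

#' @export
print.dataset_split <- function(x, ...) {
  cat(sprintf("<dataset_split train=%d validation=%d test=%d>\n",
              length(x$train), length(x$validation), length(x$test)))
  invisible(x)
}

#' Load a generated dataset from a manifest
#'
#' Reads image/mask pairs listed in a [generate_dataset()] manifest,
#' attaching the weather/height metadata used for stratified evaluation.
#' Split membership comes from the manifest's `split` column.
#'
#' @param dir dataset directory containing the PNGs and `manifest.csv`.
#' @param split optional: keep only rows with this split label.
#' @param manifest optional manifest data.frame (read from disk by default).
#' @return A list of pairs; each pair is a list with `image`, `mask`, `id`,
#'   `weather`, `height_m`, `true_coverage_pct`, `split`.
#' @export
load_dataset <- function(dir, split = NULL, manifest = NULL) {
  if (is.null(manifest)) {
    mp <- file.path(dir, "manifest.csv")
    if (!file.exists(mp)) stop_input("no manifest found at '%s'", mp)
    manifest <- read.csv(mp, stringsAsFactors = FALSE)
  }
  if (!is.null(split)) manifest <- manifest[manifest$split == split, , drop = FALSE]
  lapply(seq_len(nrow(manifest)), function(i) {
    row <- manifest[i, ]
    pr <- load_pair(file.path(dir, row$filename),
                    file.path(dir, mask_filename(row$filename)),
                    weather = row$weather, height_m = row$height_m,
                    source_id = row$filename)
    list(image = pr$image, mask = pr$mask, id = row$filename,
         weather = row$weather, height_m = row$height_m,
         true_coverage_pct = row$true_coverage_pct, split = row$split)
  })
}
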