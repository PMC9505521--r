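#' Field image with acquisition metadata
#'
#' An RGB raster of a cotton-field surface together with the acquisition
#' metadata the evaluation stratifies over (weather condition and UAV flight
#' height).  Pixels are stored as an `H x W x 3` numeric array with values in
#' `[0, 255]`, rows = image rows (origin top-left).  Note the field convention
#' of quoting sizes as width x height; array dimensions are always
#' (rows = height, cols = width).
#'
#' @param pixels `H x W x 3` numeric array, values in `[0, 255]`.
#' @param weather one of `"sunny"`, `"cloudy"`, `"unknown"`.
#' @param height_m acquisition height in metres, or `NA` when unknown.
#' @param source_id identifier carried through reports.
#' @return An object of class `field_image`.
#' @export
field_image <- function(pixels, weather = "unknown", height_m = NA_real_,
                        source_id = "") {
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3] != 3L) {
    stop_input("field image pixels must be an H x W x 3 array")
  }
  if (min(pixels) < 0 || max(pixels) > 255) {
    stop_input("field image pixel values must lie in [0, 255]")
  }
  weather <- match.arg(weather, c("sunny", "cloudy", "unknown"))
  structure(
    list(pixels = pixels, weather = weather, height_m = height_m,
         source_id = source_id),
    class = "field_image"
  )
}

#' Binary film/background mask
#'
#' Per-pixel labels with film = 1 (the positive class) and background = 0;
#' the unit of both ground truth and prediction.  On disk masks are
#' single-channel PNGs with values `{0, 255}`; in memory they are `{0, 1}`
#' integer matrices.
#'
#' @param labels integer/numeric matrix with values in `{0, 1}`.
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(labels) {
  if (!is.matrix(labels)) stop_input("mask labels must be a matrix")
  bad <- setdiff(unique(as.vector(labels)), c(0, 1))
  if (length(bad) > 0) {
    stop_input("mask contains values other than {0, 1}: %s",
               paste(utils::head(bad, 8), collapse = ", "))
  }
  structure(list(labels = matrix(as.integer(labels), nrow(labels), ncol(labels))),
            class = "binary_mask")
}

#' @export
print.field_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<field_image %dx%d px, weather=%s, height=%s m, id='%s'>\n",
              d[2], d[1], x$weather,
              ifelse(is.na(x$height_m), "?", format(x$height_m)), x$source_id))
  invisible(x)
}

#' @export
print.binary_mask <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("<binary_mask %dx%d px, %.3f%% film>\n", d[2], d[1],
              100 * sum(x$labels) / length(x$labels)))
  invisible(x)
}

# Accept either a binary_mask or a bare {0,1} matrix.
mask_labels <- function(x) {
  if (inherits(x, "binary_mask")) return(x$labels)
  if (is.matrix(x)) return(binary_mask(x)$labels)
  stop_input("expected a binary_mask or a {0,1} matrix")
}

image_pixels <- function(x) {
  if (inherits(x, "field_image")) return(x$pixels)
  if (is.array(x) && length(dim(x)) == 3L) return(x)
  stop_input("expected a field_image or an H x W x 3 array")
}
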