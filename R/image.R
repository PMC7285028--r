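#' RGB quadrat image
#'
#' A quadrat photograph is stored as a `height x width x 3` numeric array of
#' red, green and blue intensities on the 0--255 scale, tagged with the light
#' condition under which it was taken (`"sunny"` or `"cloudy"`). The condition
#' tag selects which reference file a supervised classification uses.
#'
#' @param pixels Numeric array of dimension `c(height, width, 3)` with values
#'   in `[0, 255]`.
#' @param condition Light condition, `"sunny"` or `"cloudy"`.
#' @return An `rgb_image` object (the array with a `condition` attribute).
#' @export
rgb_image <- function(pixels, condition = c("cloudy", "sunny")) {
  condition <- match.arg(condition)
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3] != 3L) {
    abort("`pixels` must be a height x width x 3 array.")
  }
  if (any(pixels < 0 | pixels > 255)) {
    abort("Pixel intensities must lie in [0, 255].")
  }
  structure(pixels, condition = condition, class = c("rgb_image", "array"))
}

#' @export
print.rgb_image <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<rgb_image> %d x %d, condition: %s\n", d[1], d[2],
              image_condition(x)))
  invisible(x)
}

#' @rdname rgb_image
#' @param image An `rgb_image`.
#' @export
image_condition <- function(image) {
  attr(image, "condition") %||% "cloudy"
}

#' Crop an image to a rectangular window
#'
#' Optional step mirroring the clipping of photographs to the quadrat frame
#' before classification.
#'
#' @param image An [rgb_image()].
#' @param rows,cols Integer ranges (inclusive) to retain.
#' @return The cropped `rgb_image`.
#' @export
crop_image <- function(image, rows, cols) {
  d <- dim(image)
  if (min(rows) < 1 || max(rows) > d[1] || min(cols) < 1 || max(cols) > d[2]) {
    abort("Crop window exceeds image bounds.")
  }
  rgb_image(unclass(image)[rows, cols, , drop = FALSE],
            condition = image_condition(image))
}

#' Label raster
#'
#' Per-pixel class assignments produced by a classifier: an integer matrix of
#' indices into an ordered label vector.
#'
#' @param assignments Integer matrix of label indices (1-based).
#' @param labels Character vector of class labels.
#' @return A `label_raster` object.
#' @export
label_raster <- function(assignments, labels) {
  assignments <- matrix(as.integer(assignments), nrow = nrow(assignments))
  if (any(assignments < 1L | assignments > length(labels))) {
    abort("Raster contains indices outside the label set.")
  }
  structure(assignments, labels = as.character(labels),
            class = c("label_raster", "matrix"))
}

#' @export
print.label_raster <- function(x, ...) {
  cat(sprintf("<label_raster> %d x %d, labels: %s\n", nrow(x), ncol(x),
              paste(raster_labels(x), collapse = ", ")))
  invisible(x)
}

#' @rdname label_raster
#' @param raster A `label_raster`.
#' @export
raster_labels <- function(raster) attr(raster, "labels")

#' Read and write images as PNG
#'
#' Images are exchanged as 8-bit RGB PNG files; binary masks as single-channel
#' PNG with weed pixels at 255.
#'
#' @param image An [rgb_image()].
#' @param path File path.
#' @param condition Condition tag to attach on read.
#' @return `write_image_png()` returns `path` invisibly; `read_image_png()`
#'   returns an `rgb_image`; mask functions the analogous logical matrix.
#' @export
write_image_png <- function(image, path) {
  arr <- unclass(image) / 255
  png::writePNG(arr, target = path)
  invisible(path)
}

#' @rdname write_image_png
#' @export
read_image_png <- function(path, condition = c("cloudy", "sunny")) {
  arr <- png::readPNG(path)
  if (length(dim(arr)) == 2L) arr <- array(rep(arr, 3), dim = c(dim(arr), 3))
  rgb_image(round(arr[, , 1:3, drop = FALSE] * 255),
            condition = match.arg(condition))
}

#' @rdname write_image_png
#' @param mask Logical matrix.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask), nrow(mask)), target = path)
  invisible(path)
}

#' @rdname write_image_png
#' @export
read_mask_png <- function(path) {
  arr <- png::readPNG(path)
  if (length(dim(arr)) == 3L) arr <- arr[, , 1]
  arr > 0.5
}
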