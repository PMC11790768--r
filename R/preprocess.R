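#' Unfolded rib-cage image container
#'
#' A 2-D grayscale intensity grid (numeric matrix, values in \[0, 255\],
#' row-major with origin at the top-left) standing for one unfolded rib cage,
#' together with a provenance id and a processing stage.
#'
#' All coordinates in this package are 1-based: `x` indexes columns (left to
#' right), `y` indexes rows (top to bottom), matching R's matrix convention.
#'
#' @param pixels Numeric matrix of intensities in \[0, 255\].
#' @param image_id Character scalar identifying the source image.
#' @param stage One of `"raw"`, `"cropped"`, `"large"`.
#' @return An `unfolded_image` object (a matrix with `image_id` and `stage`
#'   attributes).
#' @export
unfolded_image <- function(pixels, image_id, stage = c("raw", "cropped", "large")) {
  stage <- match.arg(stage)
  stopifnot(is.matrix(pixels), is.numeric(pixels))
  if (any(pixels < 0 | pixels > 255)) {
    stop("pixel intensities must lie in [0, 255]")
  }
  structure(pixels, image_id = as.character(image_id), stage = stage,
            class = c("unfolded_image", "matrix"))
}

#' @export
print.unfolded_image <- function(x, ...) {
  cat(sprintf("<unfolded_image '%s'> stage=%s, %d x %d px, range [%g, %g]\n",
              attr(x, "image_id"), attr(x, "stage"), nrow(x), ncol(x),
              min(x), max(x)))
  invisible(x)
}

image_id <- function(img) attr(img, "image_id")
image_stage <- function(img) attr(img, "stage")

#' Crop window specification
#'
#' Defines the axis-aligned window cut out of a raw unfolded image to remove
#' background. Defaults to the 500-row by 1000-column geometry used for all
#' downstream mining.
#'
#' @param top,left 1-based row/column of the window's top-left corner.
#' @param height,width Window size in pixels.
#' @return A `crop_spec` list.
#' @export
crop_spec <- function(top = 1L, left = 1L, height = 500L, width = 1000L) {
  spec <- list(top = as.integer(top), left = as.integer(left),
               height = as.integer(height), width = as.integer(width))
  stopifnot(spec$top >= 1L, spec$left >= 1L, spec$height >= 1L, spec$width >= 1L)
  structure(spec, class = "crop_spec")
}

#' Crop a raw unfolded image
#'
#' Output pixel (r, c) equals input pixel (r + top - 1, c + left - 1); the
#' result has exactly the window's shape.
#'
#' @param img An `unfolded_image` at stage `"raw"`.
#' @param spec A [crop_spec()]; must lie fully inside `img`.
#' @return An `unfolded_image` at stage `"cropped"`.
#' @export
crop_image <- function(img, spec = crop_spec()) {
  stopifnot(inherits(spec, "crop_spec"))
  bottom <- spec$top + spec$height - 1L
  right <- spec$left + spec$width - 1L
  if (bottom > nrow(img) || right > ncol(img)) {
    stop(sprintf(
      "crop window [%d:%d, %d:%d] exceeds image bounds (%d x %d)",
      spec$top, bottom, spec$left, right, nrow(img), ncol(img)))
  }
  unfolded_image(unclass(img)[spec$top:bottom, spec$left:right, drop = FALSE],
                 image_id(img), stage = "cropped")
}

#' Upscale an image by pixel-area-relation resampling
#'
#' Resamples using the pixel-area relation. For an integer enlargement factor
#' every output pixel's area falls inside exactly one source pixel, so the
#' operation is exact block replication: each source pixel becomes a
#' `factor` x `factor` block of its own intensity. `factor = 1` is the
#' identity; constant regions keep their intensity exactly.
#'
#' @param img An `unfolded_image` (stage `"cropped"` in the standard pipeline).
#' @param factor Integer enlargement factor, >= 1 (default 3, giving
#'   1500 x 3000 "large" images from the default crop).
#' @return An `unfolded_image` at stage `"large"` with shape
#'   `dim(img) * factor`.
#' @export
upscale_image <- function(img, factor = 3L) {
  factor <- as.integer(factor)
  if (is.na(factor) || factor < 1L) stop("upscale factor must be an integer >= 1")
  px <- unclass(img)
  out <- if (factor == 1L) px else kronecker(px, matrix(1, factor, factor))
  unfolded_image(out, image_id(img), stage = "large")
}

#' Map raw-frame coordinates to the large-image frame
#'
#' Maps a pixel (x, y) of the raw frame, lying inside the crop window, to the
#' centre of its `factor` x `factor` block in the upscaled ("large") image:
#' `X = (x - left) * factor + (factor + 1) / 2`, rounded to the nearest
#' integer (exact for odd factors), and analogously for `y` with `top`.
#'
#' @param x,y 1-based column/row in the raw frame (inside the crop window).
#' @param spec The [crop_spec()] used for cropping.
#' @param factor Integer upscale factor.
#' @return A list with integer vectors `X` (column) and `Y` (row) in the
#'   large-image frame.
#' @export
#' @examples
#' to_large_coords(11, 1, crop_spec(top = 1, left = 1), factor = 3) # X = 32
to_large_coords <- function(x, y, spec = crop_spec(), factor = 3L) {
  factor <- as.integer(factor)
  stopifnot(factor >= 1L, length(x) == length(y))
  inside <- x >= spec$left & x <= spec$left + spec$width - 1L &
    y >= spec$top & y <= spec$top + spec$height - 1L
  if (!all(inside)) {
    stop("coordinate(s) outside the crop window: ",
         paste(sprintf("(%d,%d)", x[!inside], y[!inside]), collapse = " "))
  }
  half <- (factor + 1) / 2
  list(X = as.integer(round((x - spec$left) * factor + half)),
       Y = as.integer(round((y - spec$top) * factor + half)))
}

#' Invert the large-frame mapping back to raw-frame coordinates
#'
#' Recovers the raw-frame pixel whose block contains the large-frame
#' coordinate (exact round trip for coordinates produced by
#' [to_large_coords()]).
#'
#' @inheritParams to_large_coords
#' @param X,Y 1-based large-frame column/row.
#' @return A list with integer vectors `x` and `y` in the raw frame.
#' @export
from_large_coords <- function(X, Y, spec = crop_spec(), factor = 3L) {
  factor <- as.integer(factor)
  list(x = as.integer((X - 1L) %/% factor) + spec$left,
       y = as.integer((Y - 1L) %/% factor) + spec$top)
}

#' Read / write grayscale PNG images
#'
#' Thin wrappers around the png package keeping the \[0, 255\] intensity
#' convention and the `unfolded_image` attributes.
#'
#' @param path File path.
#' @param image_id Id recorded on the read image (default: file name sans
#'   extension).
#' @param stage Stage recorded on the read image.
#' @return `read_unfolded()` returns an `unfolded_image`; `write_unfolded()`
#'   returns `path` invisibly.
#' @export
read_unfolded <- function(path, image_id = NULL,
                          stage = c("raw", "cropped", "large")) {
  stage <- match.arg(stage)
  px <- png::readPNG(path)
  if (length(dim(px)) == 3L) px <- px[, , 1L]  # collapse grayscale-with-alpha
  unfolded_image(round(px * 255),
                 image_id %||% sub("\\.[^.]+$", "", basename(path)),
                 stage = stage)
}

#' @rdname read_unfolded
#' @param img An `unfolded_image`.
#' @export
write_unfolded <- function(img, path) {
  png::writePNG(unclass(img) / 255, path)
  invisible(path)
}
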