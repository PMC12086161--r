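#' RGB image containers and PNG input/output
#'
#' Images are plain numeric arrays of dimension `H x W x 3` holding 8-bit
#' intensities in `[0, 255]`, indexed `[row, col, channel]` with channels
#' ordered R, G, B. Pixel coordinates throughout the package are 0-based:
#' the pixel in matrix row `r`, column `c` (1-based R indexing) has
#' coordinates `x = c - 1`, `y = r - 1`. Boxes are half-open,
#' `[x_min, x_max) x [y_min, y_max)`, so a pixel belongs to a box iff its
#' 0-based index falls inside the half-open range.
#'
#' @param pixels numeric array `H x W x 3`, values in `[0, 255]`.
#' @return `rgb_image()` returns the validated array (invisibly classed
#'   `"rgb_image"` for plotting).
#' @examples
#' img <- rgb_image(array(128, dim = c(4, 6, 3)))
#' dim(img)
#' @export
rgb_image <- function(pixels) {
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3] != 3L) {
    stop("`pixels` must be an H x W x 3 array (R, G, B channels)",
         call. = FALSE)
  }
  if (dim(pixels)[1] < 1L || dim(pixels)[2] < 1L) {
    stop("image must have height >= 1 and width >= 1", call. = FALSE)
  }
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255) {
    stop("pixel intensities must lie in [0, 255]", call. = FALSE)
  }
  structure(pixels, class = c("rgb_image", class(pixels)))
}

#' @rdname rgb_image
#' @param path file path of a PNG image.
#' @export
read_image_png <- function(path) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 2L) px <- array(rep(px, 3L), dim = c(dim(px), 3L))
  if (dim(px)[3] > 3L) px <- px[, , 1:3, drop = FALSE]
  rgb_image(round(px * 255))
}

#' @rdname rgb_image
#' @param image an `rgb_image` (or bare `H x W x 3` array).
#' @export
write_image_png <- function(image, path) {
  px <- unclass(image) / 255
  png::writePNG(px, target = path)
  invisible(path)
}

#' Write a binary mask as a single-channel PNG (0/255)
#'
#' @param mask logical (or 0/1) matrix.
#' @param path output file path.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask != 0), nrow(mask), ncol(mask)),
                target = path)
  invisible(path)
}

#' Read a 0/255 (or 0/1) single-channel PNG back into a logical mask
#'
#' @param path file path of the mask PNG.
#' @export
read_mask_png <- function(path) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 3L) px <- px[, , 1]
  px > 0.5
}

#' Write a real-valued map (e.g. an Excess-Green map) as 16-bit PNG
#'
#' The map is linearly rescaled to `[0, 1]` for storage; intended for
#' visual inspection, not round-tripping exact values.
#'
#' @param map numeric matrix.
#' @param path output file path.
#' @export
write_map_png <- function(map, path) {
  rng <- range(map)
  scaled <- if (rng[2] > rng[1]) (map - rng[1]) / (rng[2] - rng[1]) else map * 0
  png::writePNG(scaled, target = path)
  invisible(path)
}

# crop a half-open pixel box out of an image/matrix; box already clipped
crop_pixels <- function(x, box) {
  rows <- (ceiling(box$y_min) + 1L):ceiling(box$y_max)
  cols <- (ceiling(box$x_min) + 1L):ceiling(box$x_max)
  if (length(dim(x)) == 3L) x[rows, cols, , drop = FALSE] else x[rows, cols, drop = FALSE]
}
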