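## Image conventions used throughout the package:
##  - a grayscale image is a numeric matrix, rows = y (row 1 at the top),
##    columns = x, intensities on the 0..255 scale;
##  - a colour image is an h x w x 3 array on the same scale;
##  - pixel centres sit at integer (x, y) coordinates starting at (1, 1).

#' Read an image from a PNG file
#'
#' Returns a grayscale matrix (or an h x w x 3 array if `gray = FALSE` and
#' the file has colour channels), intensities scaled to 0..255.
#'
#' @param path path to a PNG file.
#' @param gray collapse colour channels to luminance?
#' @return numeric matrix (grayscale) or array (colour).
#' @export
read_image <- function(path, gray = TRUE) {
  a <- png::readPNG(path) * 255
  if (length(dim(a)) == 3L) {
    if (dim(a)[3] == 4L) a <- a[, , 1:3, drop = FALSE]  # drop alpha
    if (gray) a <- to_gray(a)
  }
  a
}

#' Write an image to a PNG file
#'
#' @param image grayscale matrix or colour array on the 0..255 scale.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  png::writePNG(pmin(pmax(image / 255, 0), 1), path)
  invisible(path)
}

#' Convert an image to grayscale
#'
#' Colour images are collapsed with the Rec. 601 luminance weights;
#' grayscale matrices pass through unchanged.
#'
#' @param image matrix or h x w x 3 array on the 0..255 scale.
#' @return numeric matrix.
#' @export
to_gray <- function(image) {
  if (is.matrix(image)) return(image)
  stopifnot(length(dim(image)) == 3L)
  0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
}

## 90-degree clockwise rotation of a matrix image.
rot90_cw <- function(m) t(m)[, nrow(m):1, drop = FALSE]

#' Rotate an image by a right angle
#'
#' @param image grayscale matrix.
#' @param k number of 90-degree clockwise turns (0..3).
#' @return rotated matrix.
#' @export
rotate_image <- function(image, k) {
  k <- as.integer(k) %% 4L
  for (i in seq_len(k)) image <- rot90_cw(image)
  image
}
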