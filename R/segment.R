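## Segmentation and physical measurement: isolate the organism, binarize
## with Otsu's method, suppress the marker region, extract external
## contours, filter by physical area and measure area / width / height in
## centimetres.

#' Otsu's threshold of a grayscale image
#'
#' Maximizes the between-class variance of the 256-bin intensity histogram.
#' The returned threshold `t` splits intensities into a dark class
#' (`<= t`) and a light class (`> t`); ties are broken toward the lowest
#' threshold.
#'
#' @param image grayscale matrix on the 0..255 scale.
#' @return integer threshold in 0..254.
#' @export
otsu_threshold <- function(image) {
  v <- round(as.vector(to_gray(image)))
  if (min(v) == max(v))
    stop("cannot threshold a constant image: no between-class variance exists")
  h <- tabulate(v + 1L, nbins = 256L)
  p <- h / sum(h)
  omega <- cumsum(p)                    # weight of the dark class at t = 0..255
  mu <- cumsum(p * (0:255))             # first moment of the dark class
  mu_t <- mu[256]
  t_all <- 0:254
  w0 <- omega[t_all + 1L]
  sigma_b <- (mu_t * w0 - mu[t_all + 1L])^2 / (w0 * (1 - w0))
  sigma_b[!is.finite(sigma_b)] <- -Inf
  t_all[which.max(sigma_b)]
}

#' Binarize an image with Otsu's method
#'
#' Colour input is converted to grayscale first. The foreground is the
#' darker class, matching dark organisms on a light background.
#'
#' @param image grayscale matrix or colour array.
#' @return logical matrix (`TRUE` = foreground) with the chosen threshold
#'   attached as attribute `"threshold"`.
#' @export
binarize <- function(image) {
  g <- to_gray(image)
  t <- otsu_threshold(g)
  structure(g <= t, threshold = t)
}

#' Replace the background of an image with white
#'
#' The self-contained `"threshold"` backend applies a global intensity cut
#' at the image's Otsu threshold and paints the light class white, leaving
#' the dark foreground untouched. The `"matting"` backend slot exists for
#' an external trimap/matting model and is not bundled.
#'
#' @param image grayscale matrix or colour array.
#' @param backend `"threshold"` or `"matting"`.
#' @return image of the same kind with background pixels set to white
#'   (255); no alpha channel is introduced.
#' @export
remove_background <- function(image, backend = c("threshold", "matting")) {
  backend <- match.arg(backend)
  if (backend == "matting")
    stop("the matting backend requires an external model and is not ",
         "bundled; use backend = \"threshold\"")
  g <- to_gray(image)
  if (min(g) == max(g)) {
    if (g[1] < 128)
      warning("constant dark image: no background found, everything retained as foreground")
    return(image)
  }
  t <- otsu_threshold(g)
  bg <- g > t
  if (is.matrix(image)) {
    image[bg] <- 255
  } else {
    for (ch in 1:3) {
      pl <- image[, , ch]; pl[bg] <- 255; image[, , ch] <- pl
    }
  }
  image
}

#' Blank out the fiducial-marker region of a binary mask
#'
#' The marker is dark and would otherwise be measured as an object; pixels
#' inside its quadrilateral, dilated by `margin_px` to swallow anti-aliased
#' edge pixels, are set to background.
#'
#' @param mask logical matrix from [binarize()].
#' @param obs a marker observation from [detect_marker()].
#' @param margin_px dilation margin in pixels.
#' @return the mask with the marker region cleared.
#' @export
mask_marker_region <- function(mask, obs, margin_px = 3) {
  quad <- obs$corners
  xs <- max(1L, floor(min(quad[, 1]) - margin_px)):min(ncol(mask), ceiling(max(quad[, 1]) + margin_px))
  ys <- max(1L, floor(min(quad[, 2]) - margin_px)):min(nrow(mask), ceiling(max(quad[, 2]) + margin_px))
  if (length(xs) == 0L || length(ys) == 0L) return(mask)
  X <- as.vector(matrix(xs, length(ys), length(xs), byrow = TRUE))
  Y <- as.vector(matrix(ys, length(ys), length(xs)))
  inside <- point_in_polygon(X, Y, quad)
  if (margin_px > 0) {
    near <- rep(FALSE, length(X))
    n <- nrow(quad)
    for (i in seq_len(n)) {
      a <- quad[i, ]; b <- quad[if (i == n) 1L else i + 1L, ]
      ab <- b - a
      tt <- pmin(pmax(((X - a[1]) * ab[1] + (Y - a[2]) * ab[2]) / sum(ab^2), 0), 1)
      near <- near | ((X - a[1] - tt * ab[1])^2 + (Y - a[2] - tt * ab[2])^2 <= margin_px^2)
    }
    inside <- inside | near
  }
  patch <- mask[ys, xs]
  patch[matrix(inside, length(ys), length(xs))] <- FALSE
  mask[ys, xs] <- patch
  mask
}

#' Measure segmented objects in physical units
#'
#' Labels connected foreground components, extracts each component's
#' external contour (holes are ignored), computes the contour's shoelace
#' pixel area, converts to cm2 with the calibration, and drops objects
#' below the minimum physical area (the boundary is kept: `>=`). Results
#' are sorted by area, largest first.
#'
#' @param mask logical matrix (`TRUE` = foreground).
#' @param cal a [compute_scale()] calibration.
#' @param min_area_cm2 minimum physical area retained, in cm2.
#' @return a list of `segmented_object`s, each with `contour` (pixel
#'   polygon), `pixel_area` (shoelace, px2), `pixel_count` (raster count),
#'   `area_cm2`, `bbox` (xmin, xmax, ymin, ymax), `width_cm`, `height_cm`.
#' @export
measure_objects <- function(mask, cal, min_area_cm2 = 5) {
  stopifnot(inherits(cal, "scale_calibration"))
  lab <- EBImage::bwlabel(mask * 1L)
  nlab <- max(lab)
  out <- list()
  for (i in seq_len(nlab)) {
    idx <- which(lab == i, arr.ind = TRUE)
    ys <- range(idx[, 1]); xs <- range(idx[, 2])
    sub <- lab[ys[1]:ys[2], xs[1]:xs[2], drop = FALSE] == i
    ct <- outer_contour(sub)
    if (is.null(ct)) next
    ct[, 1] <- ct[, 1] + xs[1] - 1
    ct[, 2] <- ct[, 2] + ys[1] - 1
    pixel_area <- abs(shoelace_area(ct))
    area_cm2 <- pixels_to_cm2(pixel_area, cal)
    bbox <- c(xmin = min(ct[, 1]), xmax = max(ct[, 1]),
              ymin = min(ct[, 2]), ymax = max(ct[, 2]))
    obj <- structure(list(
      contour = ct,
      pixel_area = pixel_area,
      pixel_count = nrow(idx),
      area_cm2 = area_cm2,
      bbox = bbox,
      width_cm = unname(bbox["xmax"] - bbox["xmin"]) / cal$pixels_per_cm,
      height_cm = unname(bbox["ymax"] - bbox["ymin"]) / cal$pixels_per_cm,
      mask = sub, mask_offset = c(x = xs[1], y = ys[1])),
      class = "segmented_object")
    out[[length(out) + 1L]] <- obj
  }
  keep <- vapply(out, function(o) o$area_cm2 >= min_area_cm2, logical(1))
  out <- out[keep]
  out[order(vapply(out, function(o) o$area_cm2, numeric(1)), decreasing = TRUE)]
}

#' @export
print.segmented_object <- function(x, ...) {
  cat(sprintf("segmented object: area %.2f cm2, bbox %.1f x %.1f cm, %d px\n",
              x$area_cm2, x$width_cm, x$height_cm, x$pixel_count))
  invisible(x)
}
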