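## Fiducial-marker detection and pixel-to-centimetre calibration.
##
## Candidate quadrilaterals are dark connected components whose external
## contour reduces to a convex quad; the module grid is sampled through a
## homography and matched against the dictionary pattern under all four
## right-angle rotations, which both identifies the marker and resolves
## its orientation so corners can be reported in a fixed cyclic order
## (canonical top-left first, then clockwise).

## four-point homography mapping (u, v) in the unit square to image (x, y)
.homography_from_unit_square <- function(quad) {
  src <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  A <- matrix(0, 8, 8); b <- numeric(8)
  for (i in 1:4) {
    u <- src[i, 1]; v <- src[i, 2]; x <- quad[i, 1]; y <- quad[i, 2]
    A[2 * i - 1, ] <- c(u, v, 1, 0, 0, 0, -u * x, -v * x)
    A[2 * i, ]     <- c(0, 0, 0, u, v, 1, -u * y, -v * y)
    b[2 * i - 1] <- x; b[2 * i] <- y
  }
  h <- solve(A, b)
  matrix(c(h, 1), 3, 3, byrow = TRUE)
}

.apply_homography <- function(H, u, v) {
  d <- H[3, 1] * u + H[3, 2] * v + H[3, 3]
  cbind(x = (H[1, 1] * u + H[1, 2] * v + H[1, 3]) / d,
        y = (H[2, 1] * u + H[2, 2] * v + H[2, 3]) / d)
}

## max-area quadrilateral spanned by points on a convex hull
.quad_corners <- function(pts) {
  hull <- pts[chull(pts), , drop = FALSE]
  n <- nrow(hull)
  if (n < 4L) return(NULL)
  ## diagonal: farthest pair
  d2 <- as.matrix(stats::dist(hull))^2
  ij <- which(d2 == max(d2), arr.ind = TRUE)[1, ]
  p1 <- hull[ij[1], ]; p3 <- hull[ij[2], ]
  ## split remaining hull points by side of the diagonal, take the point
  ## with maximal triangle area on each side
  cr <- (p3[1] - p1[1]) * (hull[, 2] - p1[2]) - (p3[2] - p1[2]) * (hull[, 1] - p1[1])
  if (!any(cr > 0) || !any(cr < 0)) return(NULL)
  p2 <- hull[which.max(ifelse(cr > 0, abs(cr), -Inf)), ]
  p4 <- hull[which.max(ifelse(cr < 0, abs(cr), -Inf)), ]
  quad <- rbind(p1, p2, p3, p4)
  ## order clockwise (image coordinates, y down) around the centroid
  ctr <- colMeans(quad)
  quad[order(atan2(quad[, 2] - ctr[2], quad[, 1] - ctr[1])), , drop = FALSE]
}

## Sub-pixel corner refinement: assign contour points to the nearest quad
## side, drop points near the corners, fit a total-least-squares line per
## side, and intersect consecutive lines.
.refine_corners <- function(contour, quad, corner_exclusion = 4) {
  n <- 4L
  lines <- vector("list", n)
  for (i in seq_len(n)) {
    a <- quad[i, ]; b <- quad[if (i == n) 1L else i + 1L, ]
    ab <- b - a; len2 <- sum(ab^2)
    tt <- ((contour[, 1] - a[1]) * ab[1] + (contour[, 2] - a[2]) * ab[2]) / len2
    dx <- contour[, 1] - a[1] - tt * ab[1]
    dy <- contour[, 2] - a[2] - tt * ab[2]
    d <- sqrt(dx^2 + dy^2)
    frac <- corner_exclusion / sqrt(len2)
    sel <- d < 1.5 & tt > frac & tt < 1 - frac
    if (sum(sel) < 4L) return(quad)  # not enough support for a fit
    p <- contour[sel, , drop = FALSE]
    ctr <- colMeans(p)
    ev <- eigen(stats::cov(p), symmetric = TRUE)
    dir <- ev$vectors[, 1]
    lines[[i]] <- list(p0 = ctr, dir = dir)
  }
  out <- quad
  for (i in seq_len(n)) {
    l1 <- lines[[if (i == 1L) n else i - 1L]]; l2 <- lines[[i]]
    M <- cbind(l1$dir, -l2$dir)
    if (abs(det(M)) < 1e-8) return(quad)
    tt <- solve(M, l2$p0 - l1$p0)
    out[i, ] <- l1$p0 + tt[1] * l1$dir
  }
  out
}

## sample the ng x ng module grid through the homography; bit = dark (1)
.sample_modules <- function(gray, H, ng, threshold) {
  off <- c(-0.22, 0, 0.22)
  grid <- expand.grid(c = seq_len(ng), r = seq_len(ng))
  vals <- matrix(0, nrow(grid), length(off)^2)
  k <- 0L
  for (ou in off) for (ov in off) {
    k <- k + 1L
    u <- (grid$c - 0.5 + ou) / ng
    v <- (grid$r - 0.5 + ov) / ng
    xy <- .apply_homography(H, u, v)
    xi <- pmin(pmax(round(xy[, 2]), 1L), nrow(gray))
    yi <- pmin(pmax(round(xy[, 1]), 1L), ncol(gray))
    vals[, k] <- gray[cbind(xi, yi)]
  }
  matrix(as.integer(rowMeans(vals) <= threshold), ng, ng, byrow = TRUE)
}

#' Detect a square fiducial marker and return its corners
#'
#' Finds the marker with the expected id; markers with other ids are
#' ignored silently. Corners are returned in a fixed cyclic order: the
#' marker's canonical top-left corner first, then clockwise, with
#' sub-pixel line-fit refinement.
#'
#' @param image grayscale matrix or colour array.
#' @param dictionary_name marker dictionary (default `"6x6_250"`).
#' @param expected_id id of the marker used as scale reference.
#' @param image_name label used in error messages.
#' @param min_component_px smallest dark component considered a candidate.
#' @return a `marker_observation`: list with `marker_id`, `corners`
#'   (4 x 2 matrix), `dictionary_name`.
#' @export
detect_marker <- function(image, dictionary_name = "6x6_250", expected_id = 1L,
                          image_name = "image", min_component_px = 200L) {
  g <- to_gray(image)
  if (min(g) == max(g))
    stop("no marker with id ", expected_id, " found in ", image_name,
         " (blank image)")
  t <- otsu_threshold(g)
  lab <- EBImage::bwlabel((g <= t) * 1L)
  counts <- tabulate(lab[lab > 0])
  dict <- marker_bits(dictionary_name, expected_id)
  ng <- nrow(dict) + 2L
  hits <- list()
  for (i in which(counts >= min_component_px)) {
    idx <- which(lab == i, arr.ind = TRUE)
    ys <- range(idx[, 1]); xs <- range(idx[, 2])
    sub <- lab[ys[1]:ys[2], xs[1]:xs[2], drop = FALSE] == i
    ct <- outer_contour(sub)
    if (is.null(ct) || nrow(ct) < 8L) next
    ct[, 1] <- ct[, 1] + xs[1] - 1
    ct[, 2] <- ct[, 2] + ys[1] - 1
    quad <- .quad_corners(ct)
    if (is.null(quad)) next
    ## the quad must explain essentially the whole contour (convex blob)
    if (abs(shoelace_area(quad)) < 0.85 * abs(shoelace_area(ct))) next
    quad <- .refine_corners(ct, quad)
    H <- .homography_from_unit_square(quad)
    B <- .sample_modules(g, H, ng, t)
    if (!all(B[c(1, ng), ] == 1L) || !all(B[, c(1, ng)] == 1L)) next
    inner <- B[2:(ng - 1), 2:(ng - 1)]
    for (k in 0:3) {
      if (identical(inner, dict)) {
        shift <- (4L - k) %% 4L
        ord <- ((seq_len(4L) - 1L + shift) %% 4L) + 1L
        hits[[length(hits) + 1L]] <- quad[ord, , drop = FALSE]
        break
      }
      inner <- rot90_cw(inner)
    }
  }
  if (length(hits) == 0L)
    stop("no marker with id ", expected_id, " found in ", image_name)
  if (length(hits) > 1L)
    stop("ambiguous scale: ", length(hits), " markers with id ", expected_id,
         " found in ", image_name)
  corners <- hits[[1]]
  dimnames(corners) <- list(c("TL", "TR", "BR", "BL"), c("x", "y"))
  structure(list(marker_id = as.integer(expected_id), corners = corners,
                 dictionary_name = dictionary_name),
            class = "marker_observation")
}

#' Derive the pixels-per-centimetre scale from a marker observation
#'
#' The scale is the arithmetic mean of the quadrilateral's four side
#' lengths divided by the marker's physical side length. Perspective skew
#' (max/min side ratio above `skew_threshold`) triggers a warning, not an
#' error: the imaging protocol is top-view and skew is only diagnosed.
#'
#' @param obs a `marker_observation`.
#' @param marker_side_cm physical side length of the printed square (cm).
#' @param skew_threshold maximum tolerated max/min side-length ratio.
#' @return a `scale_calibration`: `pixels_per_cm`, `marker_side_cm`,
#'   `side_lengths_px`, `source_marker_id`, `skew_ratio`.
#' @export
compute_scale <- function(obs, marker_side_cm = 10, skew_threshold = 1.2) {
  if (!is.numeric(marker_side_cm) || marker_side_cm <= 0)
    stop("marker_side_cm must be a positive physical length")
  quad <- obs$corners
  j <- c(2:4, 1)
  sides <- sqrt(rowSums((quad[j, , drop = FALSE] - quad)^2))
  if (any(sides <= 0)) stop("degenerate marker quadrilateral: zero-length side")
  skew <- max(sides) / min(sides)
  if (skew > skew_threshold)
    warning(sprintf("marker skew ratio %.3f exceeds %.3f; top-view assumption may be violated",
                    skew, skew_threshold))
  structure(list(pixels_per_cm = mean(sides) / marker_side_cm,
                 marker_side_cm = marker_side_cm,
                 side_lengths_px = unname(sides),
                 source_marker_id = obs$marker_id,
                 skew_ratio = skew),
            class = "scale_calibration")
}

#' Convert a pixel area to square centimetres
#'
#' @param pixel_area area in px2 (non-negative).
#' @param cal a `scale_calibration`.
#' @return area in cm2.
#' @export
pixels_to_cm2 <- function(pixel_area, cal) {
  stopifnot(all(pixel_area >= 0), inherits(cal, "scale_calibration"))
  pixel_area / cal$pixels_per_cm^2
}

#' @export
print.scale_calibration <- function(x, ...) {
  cat(sprintf("scale calibration: %.3f px/cm (marker id %d, side %.1f cm, skew %.3f)\n",
              x$pixels_per_cm, x$source_marker_id, x$marker_side_cm, x$skew_ratio))
  invisible(x)
}
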