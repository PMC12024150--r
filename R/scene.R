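## Synthetic top-view scenes with exact ground truth.
##
## A scene emulates the study's imaging protocol: one dark organism and one
## square fiducial marker of known physical side length on a lighter, clean
## background, photographed from directly above. Because the scene is
## parametric, the true pixels-per-centimetre scale, the marker corners and
## the organism's pixel and physical areas are known exactly, which makes
## every downstream stage (calibration, segmentation, measurement) testable
## without photographs.

#' Construct a synthetic scene specification
#'
#' Geometry is given in centimetres and converted with `pixels_per_cm`.
#' When `image_width`/`image_height` or the object centres are `NULL`, a
#' layout is computed automatically: marker on the left, organism on the
#' right, non-overlapping, with a margin all round.
#'
#' @param pixels_per_cm ground-truth scale (pixels per centimetre).
#' @param organism list describing the organism blob: `shape` one of
#'   `"disk"` (`radius_cm`), `"ellipse"` (`semi_a_cm`, `semi_b_cm`,
#'   `angle_deg`) or `"supershape"` (`size_cm`, `m`, `n1`, `n2`, `n3` -
#'   a superformula outline sampled to a polygon), plus optional `center`
#'   (pixel coordinates) and `foreground_intensity`.
#' @param marker list: `side_cm` (physical side of the printed square,
#'   default 10), `dictionary_name`, `marker_id`, optional `center` and
#'   `rotation_deg` (clockwise).
#' @param image_width,image_height canvas size in pixels (`NULL` = auto).
#' @param background_intensity background gray level (0..255).
#' @param lighting_gradient_amplitude peak-to-peak amplitude of a linear
#'   horizontal illumination ramp added to the scene.
#' @param noise_sigma standard deviation of additive Gaussian pixel noise.
#' @param seed integer seed controlling the noise; identical specs render
#'   to bit-identical images.
#' @return an object of class `scene_spec`.
#' @export
scene_spec <- function(pixels_per_cm = 20,
                       organism = list(shape = "disk", radius_cm = 5),
                       marker = list(),
                       image_width = NULL, image_height = NULL,
                       background_intensity = 170,
                       lighting_gradient_amplitude = 0,
                       noise_sigma = 2,
                       seed = 1L) {
  stopifnot(is.numeric(pixels_per_cm), pixels_per_cm > 0)
  marker <- modifyList(list(side_cm = 10, dictionary_name = "6x6_250",
                            marker_id = 1L, center = NULL, rotation_deg = 0,
                            black_intensity = 20, white_intensity = 245),
                       marker)
  stopifnot(marker$side_cm > 0)
  organism <- modifyList(list(center = NULL, foreground_intensity = 60), organism)
  organism <- .complete_organism(organism)
  if (organism$analytic_area_cm2 <= 0)
    stop("organism has non-positive area (analytic_area_cm2 = ",
         organism$analytic_area_cm2, ")")

  ppcm <- pixels_per_cm
  margin_cm <- 1.5
  gap_cm <- 2
  ## circumscribed half-extent of the (possibly rotated) marker square
  th <- marker$rotation_deg * pi / 180
  em <- marker$side_cm / 2 * (abs(cos(th)) + abs(sin(th)))
  ro <- organism$extent_cm  # circumscribed radius of the blob

  if (is.null(image_width) || is.null(image_height)) {
    image_width  <- ceiling((margin_cm + 2 * em + gap_cm + 2 * ro + margin_cm) * ppcm)
    image_height <- ceiling((2 * margin_cm + 2 * max(em, ro)) * ppcm)
  }
  if (is.null(marker$center))
    marker$center <- c((margin_cm + em) * ppcm, image_height / 2)
  if (is.null(organism$center))
    organism$center <- c(image_width - (margin_cm + ro) * ppcm, image_height / 2)

  spec <- structure(list(
    image_width = as.integer(image_width), image_height = as.integer(image_height),
    pixels_per_cm = ppcm, marker = marker, organism = organism,
    background_intensity = background_intensity,
    lighting_gradient_amplitude = lighting_gradient_amplitude,
    noise_sigma = noise_sigma, seed = as.integer(seed)),
    class = "scene_spec")
  .validate_scene_spec(spec)
  spec
}

## fill in analytic area and circumscribed radius per shape
.complete_organism <- function(o) {
  o$shape <- match.arg(o$shape, c("disk", "ellipse", "supershape"))
  if (o$shape == "disk") {
    stopifnot(!is.null(o$radius_cm))
    o$analytic_area_cm2 <- pi * o$radius_cm^2
    o$extent_cm <- o$radius_cm
  } else if (o$shape == "ellipse") {
    stopifnot(!is.null(o$semi_a_cm), !is.null(o$semi_b_cm))
    if (is.null(o$angle_deg)) o$angle_deg <- 0
    o$analytic_area_cm2 <- pi * o$semi_a_cm * o$semi_b_cm
    o$extent_cm <- max(o$semi_a_cm, o$semi_b_cm)
  } else {
    o <- modifyList(list(size_cm = 4, m = 5, n1 = 2.2, n2 = 6, n3 = 6,
                         n_vertices = 180L), o)
    o$polygon_cm <- .supershape_polygon(o$size_cm, o$m, o$n1, o$n2, o$n3,
                                        o$n_vertices)
    o$analytic_area_cm2 <- abs(shoelace_area(o$polygon_cm))
    o$extent_cm <- max(sqrt(rowSums(o$polygon_cm^2)))
  }
  o
}

## Gielis superformula outline sampled to a closed polygon (cm coordinates,
## centred on the origin). The blob's ground-truth area is the shoelace
## area of this polygon, independent of any renderer.
.supershape_polygon <- function(size_cm, m, n1, n2, n3, n_vertices) {
  th <- seq(0, 2 * pi, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
  r <- (abs(cos(m * th / 4))^n2 + abs(sin(m * th / 4))^n3)^(-1 / n1)
  r <- r / mean(r) * size_cm
  cbind(x = r * cos(th), y = r * sin(th))
}

.marker_corners_px <- function(marker, ppcm) {
  h <- marker$side_cm / 2 * ppcm
  th <- marker$rotation_deg * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)  # clockwise, y down
  base <- rbind(c(-h, -h), c(h, -h), c(h, h), c(-h, h))      # TL TR BR BL
  sweep(base %*% t(R), 2, marker$center, "+")
}

.validate_scene_spec <- function(spec) {
  mc <- .marker_corners_px(spec$marker, spec$pixels_per_cm)
  if (any(mc[, 1] < 1) || any(mc[, 1] > spec$image_width) ||
      any(mc[, 2] < 1) || any(mc[, 2] > spec$image_height))
    stop("marker does not fit fully inside the image")
  ## overlap check on padded axis-aligned bounding boxes
  pad <- 0.25 * spec$pixels_per_cm
  ob <- spec$organism$extent_cm * spec$pixels_per_cm
  org_box <- c(spec$organism$center[1] - ob, spec$organism$center[1] + ob,
               spec$organism$center[2] - ob, spec$organism$center[2] + ob)
  mar_box <- c(range(mc[, 1]), range(mc[, 2]))
  overlap <- !(org_box[2] + pad < mar_box[1] || mar_box[2] + pad < org_box[1] ||
               org_box[4] + pad < mar_box[3] || mar_box[4] + pad < org_box[3])
  if (overlap) stop("layout error: marker and organism footprints overlap")
  invisible(spec)
}

## logical h x w mask of pixels whose centres fall inside the organism
.organism_mask <- function(spec) {
  o <- spec$organism
  ppcm <- spec$pixels_per_cm
  X <- matrix(seq_len(spec$image_width), spec$image_height, spec$image_width,
              byrow = TRUE)
  Y <- matrix(seq_len(spec$image_height), spec$image_height, spec$image_width)
  dx <- (X - o$center[1]) / ppcm
  dy <- (Y - o$center[2]) / ppcm
  if (o$shape == "disk") {
    dx * dx + dy * dy <= o$radius_cm^2
  } else if (o$shape == "ellipse") {
    th <- o$angle_deg * pi / 180
    u <- dx * cos(th) + dy * sin(th)
    v <- -dx * sin(th) + dy * cos(th)
    (u / o$semi_a_cm)^2 + (v / o$semi_b_cm)^2 <= 1
  } else {
    dim(dx) <- NULL; dim(dy) <- NULL
    m <- matrix(point_in_polygon(dx, dy, o$polygon_cm),
                spec$image_height, spec$image_width)
    m
  }
}

#' Render a synthetic scene
#'
#' Paints the marker and the organism on the background, applies the
#' lighting ramp and seeded Gaussian noise, and quantizes to 8 bits. The
#' returned ground truth is exact: marker corners from the spec geometry,
#' organism pixel area by counting rasterized foreground pixels.
#'
#' @param spec a [scene_spec()].
#' @return a list with elements `image` (grayscale matrix) and `truth`
#'   (list: `marker_corners`, `true_pixels_per_cm`,
#'   `true_object_pixel_area`, `analytic_area_cm2`).
#' @export
render_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  .validate_scene_spec(spec)
  h <- spec$image_height; w <- spec$image_width
  img <- matrix(spec$background_intensity, h, w)

  ## organism
  fg <- .organism_mask(spec)
  img[fg] <- spec$organism$foreground_intensity

  ## marker: inverse-map pixels in its bounding box to the module grid
  mk <- spec$marker
  ppcm <- spec$pixels_per_cm
  corners <- .marker_corners_px(mk, ppcm)
  half <- mk$side_cm / 2 * ppcm
  mods <- marker_modules(mk$dictionary_name, mk$marker_id)
  ng <- nrow(mods)
  xs <- max(1L, floor(min(corners[, 1]))):min(w, ceiling(max(corners[, 1])))
  ys <- max(1L, floor(min(corners[, 2]))):min(h, ceiling(max(corners[, 2])))
  X <- matrix(xs, length(ys), length(xs), byrow = TRUE)
  Y <- matrix(ys, length(ys), length(xs))
  th <- mk$rotation_deg * pi / 180
  ## inverse of the clockwise rotation used for the corners
  u <- (X - mk$center[1]) * cos(th) + (Y - mk$center[2]) * sin(th)
  v <- -(X - mk$center[1]) * sin(th) + (Y - mk$center[2]) * cos(th)
  inside <- abs(u) <= half & abs(v) <= half
  ci <- pmin(pmax(floor((u + half) / (2 * half) * ng) + 1L, 1L), ng)
  ri <- pmin(pmax(floor((v + half) / (2 * half) * ng) + 1L, 1L), ng)
  val <- ifelse(mods[cbind(as.vector(ri), as.vector(ci))] == 1L,
                mk$black_intensity, mk$white_intensity)
  patch <- img[ys, xs]
  patch[inside] <- val[as.vector(inside)]
  img[ys, xs] <- patch

  ## illumination ramp and seeded noise, then 8-bit quantization
  if (spec$lighting_gradient_amplitude != 0) {
    ramp <- (seq_len(w) - 1) / max(w - 1, 1) - 0.5
    img <- img + matrix(spec$lighting_gradient_amplitude * ramp, h, w, byrow = TRUE)
  }
  if (spec$noise_sigma > 0) {
    img <- img + .with_seed(spec$seed, matrix(rnorm(h * w, 0, spec$noise_sigma), h, w))
  }
  img <- round(pmin(pmax(img, 0), 255))

  list(image = img,
       truth = list(marker_corners = corners,
                    true_pixels_per_cm = ppcm,
                    true_object_pixel_area = sum(fg),
                    analytic_area_cm2 = spec$organism$analytic_area_cm2))
}

## evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state
.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Right-angle rotation augmentation
#'
#' Expands an image set by adding every right-angle orientation of each
#' input: for each image, the 0, 90, 180 and 270 degree clockwise
#' rotations, in that order, input order preserved. Fifteen base images
#' therefore become sixty.
#'
#' @param images a non-empty list of grayscale matrices (a single matrix is
#'   treated as a one-image list).
#' @return a list of `4 * length(images)` matrices.
#' @export
augment_rotations <- function(images) {
  if (is.matrix(images)) images <- list(images)
  if (!is.list(images) || length(images) == 0L)
    stop("augment_rotations() needs a non-empty list of images")
  out <- vector("list", 4L * length(images))
  j <- 0L
  for (im in images) for (k in 0:3) {
    j <- j + 1L
    out[[j]] <- rotate_image(im, k)
  }
  out
}

#' Write a rendered scene to disk
#'
#' The image is written as lossless PNG (so pixel-count ground truth
#' survives a round-trip) with a JSON ground-truth sidecar.
#'
#' @param scene result of [render_scene()].
#' @param path output PNG path; the sidecar is `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_scene <- function(scene, path) {
  write_image(scene$image, path)
  tr <- scene$truth
  tr$marker_corners <- unname(split(tr$marker_corners, row(tr$marker_corners)))
  jsonlite::write_json(tr, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Generate a batch of random scene specifications
#'
#' Draws organism shapes (disks and ellipses with projected areas spanning
#' the size range of cultured sea cucumbers, roughly 20-140 cm2) and image
#' scales uniformly from `pixels_per_cm_range`, reproducibly from `seed`.
#'
#' @param n number of scenes.
#' @param pixels_per_cm_range range to draw the true scale from.
#' @param seed integer seed.
#' @param noise_sigma,lighting_gradient_amplitude passed to [scene_spec()].
#' @return a list of `scene_spec` objects.
#' @export
generate_scenes <- function(n, pixels_per_cm_range = c(15, 40), seed = 1L,
                            noise_sigma = 2, lighting_gradient_amplitude = 10) {
  .with_seed(seed, {
    lapply(seq_len(n), function(i) {
      ppcm <- stats::runif(1, pixels_per_cm_range[1], pixels_per_cm_range[2])
      if (stats::runif(1) < 0.5) {
        org <- list(shape = "disk", radius_cm = stats::runif(1, 2.8, 6.5))
      } else {
        org <- list(shape = "ellipse",
                    semi_a_cm = stats::runif(1, 4, 8),
                    semi_b_cm = stats::runif(1, 2, 4),
                    angle_deg = stats::runif(1, 0, 180))
      }
      scene_spec(pixels_per_cm = ppcm, organism = org,
                 noise_sigma = noise_sigma,
                 lighting_gradient_amplitude = lighting_gradient_amplitude,
                 seed = sample.int(2^31 - 1, 1))
    })
  })
}
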