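## Annotated output images: segmented region filled green, bounding box in
## blue, measurement text in red - the conventional display of the
## measurement stage. Text uses a small built-in 5x7 bitmap font so no
## graphics device is needed.

.font5x7 <- local({
  def <- c(
    "0" = "01110 10001 10011 10101 11001 10001 01110",
    "1" = "00100 01100 00100 00100 00100 00100 01110",
    "2" = "01110 10001 00001 00110 01000 10000 11111",
    "3" = "01110 10001 00001 00110 00001 10001 01110",
    "4" = "00010 00110 01010 10010 11111 00010 00010",
    "5" = "11111 10000 11110 00001 00001 10001 01110",
    "6" = "01110 10000 11110 10001 10001 10001 01110",
    "7" = "11111 00001 00010 00100 01000 01000 01000",
    "8" = "01110 10001 10001 01110 10001 10001 01110",
    "9" = "01110 10001 10001 01111 00001 00001 01110",
    "." = "00000 00000 00000 00000 00000 01100 01100",
    "=" = "00000 00000 11111 00000 11111 00000 00000",
    "-" = "00000 00000 00000 11111 00000 00000 00000",
    "A" = "01110 10001 10001 11111 10001 10001 10001",
    "W" = "10001 10001 10001 10101 10101 10101 01010",
    "H" = "10001 10001 10001 11111 10001 10001 10001",
    "P" = "11110 10001 10001 11110 10000 10000 10000",
    "X" = "10001 10001 01010 00100 01010 10001 10001",
    "C" = "01110 10001 10000 10000 10000 10001 01110",
    "M" = "10001 11011 10101 10101 10001 10001 10001",
    " " = "00000 00000 00000 00000 00000 00000 00000")
  lapply(def, function(s) {
    rows <- strsplit(s, " ")[[1]]
    do.call(rbind, lapply(rows, function(r) as.integer(strsplit(r, "")[[1]]) == 1L))
  })
})

## stamp `text` onto the colour array at (x, y) top-left, in `col` (0..255)
.draw_text <- function(img, text, x, y, col, scale = 2L) {
  text <- toupper(text)
  h <- dim(img)[1]; w <- dim(img)[2]
  cx <- x
  for (ch in strsplit(text, "")[[1]]) {
    g <- .font5x7[[ch]]
    if (is.null(g)) g <- .font5x7[[" "]]
    for (r in 1:7) for (c in 1:5) if (g[r, c]) {
      ys <- y + (r - 1L) * scale + seq_len(scale) - 1L
      xs <- cx + (c - 1L) * scale + seq_len(scale) - 1L
      ys <- ys[ys >= 1 & ys <= h]; xs <- xs[xs >= 1 & xs <= w]
      if (length(ys) && length(xs)) for (k in 1:3) img[ys, xs, k] <- col[k]
    }
    cx <- cx + 6L * scale
  }
  img
}

.draw_rect <- function(img, bbox, col, lwd = 2L) {
  h <- dim(img)[1]; w <- dim(img)[2]
  x1 <- max(1, floor(bbox["xmin"])); x2 <- min(w, ceiling(bbox["xmax"]))
  y1 <- max(1, floor(bbox["ymin"])); y2 <- min(h, ceiling(bbox["ymax"]))
  for (k in 1:3) {
    img[max(1, y1 - lwd + 1):y1, x1:x2, k] <- col[k]
    img[y2:min(h, y2 + lwd - 1), x1:x2, k] <- col[k]
    img[y1:y2, max(1, x1 - lwd + 1):x1, k] <- col[k]
    img[y1:y2, x2:min(w, x2 + lwd - 1), k] <- col[k]
  }
  img
}

#' Annotate an image with measured objects
#'
#' Fills each object's segmented region, draws its bounding box and
#' overlays a text block with area (cm2), width and height (cm) and pixel
#' area. Annotation is purely cosmetic: it never feeds back into
#' measurement.
#'
#' @param image the grayscale image the objects were measured on.
#' @param objects list of `segmented_object`s from [measure_objects()].
#' @param cal the `scale_calibration` used (stored for the text overlay).
#' @param fill_col,box_col,text_col RGB triplets on the 0..255 scale
#'   (defaults: green fill, blue box, red text).
#' @param fill_alpha opacity of the region fill.
#' @return an h x w x 3 colour array.
#' @export
annotate <- function(image, objects, cal,
                     fill_col = c(0, 200, 0), box_col = c(0, 0, 255),
                     text_col = c(255, 0, 0), fill_alpha = 0.5) {
  g <- to_gray(image)
  img <- array(g, dim = c(nrow(g), ncol(g), 3))
  if (length(objects) == 0L) {
    message("no objects to annotate; image returned unchanged")
    return(img)
  }
  for (ob in objects) {
    ys <- ob$mask_offset["y"] + seq_len(nrow(ob$mask)) - 1L
    xs <- ob$mask_offset["x"] + seq_len(ncol(ob$mask)) - 1L
    for (k in 1:3) {
      patch <- img[ys, xs, k]
      patch[ob$mask] <- (1 - fill_alpha) * patch[ob$mask] + fill_alpha * fill_col[k]
      img[ys, xs, k] <- patch
    }
    img <- .draw_rect(img, ob$bbox, box_col)
    lines <- c(sprintf("A=%.2fCM2", ob$area_cm2),
               sprintf("W=%.1f H=%.1f", ob$width_cm, ob$height_cm),
               sprintf("PX=%.0f", ob$pixel_area))
    tx <- max(1L, as.integer(ob$bbox["xmin"]))
    ty <- max(1L, as.integer(ob$bbox["ymin"]) - 3L * 16L - 4L)
    for (i in seq_along(lines))
      img <- .draw_text(img, lines[i], tx, ty + (i - 1L) * 16L, text_col)
  }
  img
}
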