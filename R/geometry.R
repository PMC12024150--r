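#' Signed polygon area by the shoelace formula
#'
#' @param poly a k x 2 matrix of ordered vertex coordinates (open or
#'   closed; a repeated final vertex is handled).
#' @return signed area; take `abs()` for the geometric area.
#' @export
shoelace_area <- function(poly) {
  poly <- as.matrix(poly)
  if (nrow(poly) > 1L && all(poly[1, ] == poly[nrow(poly), ]))
    poly <- poly[-nrow(poly), , drop = FALSE]
  n <- nrow(poly)
  if (n < 3L) return(0)
  j <- c(2:n, 1L)
  sum(poly[, 1] * poly[j, 2] - poly[j, 1] * poly[, 2]) / 2
}

## perimeter of a closed polygon
polygon_perimeter <- function(poly) {
  poly <- as.matrix(poly)
  if (nrow(poly) > 1L && all(poly[1, ] == poly[nrow(poly), ]))
    poly <- poly[-nrow(poly), , drop = FALSE]
  j <- c(2:nrow(poly), 1L)
  sum(sqrt(rowSums((poly[j, , drop = FALSE] - poly)^2)))
}

#' Point-in-polygon test (even-odd rule)
#'
#' Vectorized over query points.
#'
#' @param x,y query point coordinates.
#' @param poly k x 2 matrix of ordered vertices.
#' @return logical vector.
#' @export
point_in_polygon <- function(x, y, poly) {
  poly <- as.matrix(poly)
  if (nrow(poly) > 1L && all(poly[1, ] == poly[nrow(poly), ]))
    poly <- poly[-nrow(poly), , drop = FALSE]
  n <- nrow(poly)
  inside <- logical(length(x))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > y) != (yj > y)) &
      (x < (xj - xi) * (y - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

## External iso-contour (level 0.5) of a binary matrix, returned as an
## ordered polygon in image (x = column, y = row) coordinates. The matrix
## is zero-padded first so the contour is always closed; with several
## boundary loops (holes) the one with the largest absolute shoelace area
## -- the external boundary -- is returned.
outer_contour <- function(mask) {
  m <- matrix(0, nrow(mask) + 2L, ncol(mask) + 2L)
  m[2:(nrow(mask) + 1L), 2:(ncol(mask) + 1L)] <- mask
  ## contourLines treats z[i, j] as the value at (x = i, y = j); rows of the
  ## image are y, so coordinates come back as (row, col) and are swapped.
  cl <- contourLines(seq_len(nrow(m)), seq_len(ncol(m)), m, levels = 0.5)
  if (length(cl) == 0L) return(NULL)
  polys <- lapply(cl, function(l) cbind(x = l$y - 1, y = l$x - 1))
  areas <- vapply(polys, function(p) abs(shoelace_area(p)), numeric(1))
  polys[[which.max(areas)]]
}
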