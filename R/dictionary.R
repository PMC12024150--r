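## Square fiducial-marker dictionary.
##
## A marker is an (n+2) x (n+2) module grid: a one-module black border
## around an n x n binary payload. The payload for a given (dictionary
## name, id) pair is produced by a deterministic pseudo-random generator
## keyed on both, so rendering and detection always agree on the pattern.
## Patterns are regenerated with an incremented salt until they are
## rotationally asymmetric (orientation is recoverable) and neither all
## black nor all white. Note: bit patterns are NOT byte-compatible with
## other ArUco-style dictionary implementations; within this package the
## same dictionary drives both the renderer and the detector.

## Park-Miller generator; state and outputs stay below 2^31 so arithmetic
## is exact in doubles.
.pm_next <- function(x) (16807 * x) %% 2147483647

.dict_seed <- function(dictionary_name, marker_id, salt = 0L) {
  h <- 0
  for (ch in utf8ToInt(dictionary_name)) h <- (h * 131 + ch) %% 2147483647
  h <- (h * 131 + marker_id * 7919 + salt * 104729) %% 2147483647
  if (h == 0) h <- 1
  h
}

.parse_grid_size <- function(dictionary_name) {
  m <- regmatches(dictionary_name, regexec("^([0-9]+)\\s*[xX]\\s*([0-9]+)", dictionary_name))[[1]]
  if (length(m) < 3L || m[2] != m[3])
    stop("cannot parse a square bit-grid size from dictionary name: ", dictionary_name)
  as.integer(m[2])
}

## All four right-angle rotations of a 0/1 payload matrix.
.bit_rotations <- function(bits) {
  out <- vector("list", 4L)
  out[[1]] <- bits
  for (k in 2:4) out[[k]] <- rot90_cw(out[[k - 1]])
  out
}

#' Payload bit pattern of a dictionary marker
#'
#' @param dictionary_name dictionary label encoding the payload grid size,
#'   e.g. `"6x6_250"` for a 6 x 6 payload.
#' @param marker_id non-negative integer id.
#' @return an n x n 0/1 matrix; 1 means a black module.
#' @export
marker_bits <- function(dictionary_name, marker_id) {
  n <- .parse_grid_size(dictionary_name)
  salt <- 0L
  repeat {
    x <- .dict_seed(dictionary_name, marker_id, salt)
    bits <- matrix(0L, n, n)
    for (i in seq_len(n * n)) {
      x <- .pm_next(x)
      bits[i] <- as.integer((x / 2147483647) < 0.5)
    }
    rots <- .bit_rotations(bits)
    distinct <- !any(vapply(rots[2:4], function(b) identical(b, bits), logical(1)))
    mixed <- any(bits == 0L) && any(bits == 1L)
    if (distinct && mixed) return(bits)
    salt <- salt + 1L
  }
}

## Full module grid including the black border: 1 = black, 0 = white.
marker_modules <- function(dictionary_name, marker_id) {
  bits <- marker_bits(dictionary_name, marker_id)
  n <- nrow(bits)
  g <- matrix(1L, n + 2L, n + 2L)
  g[2:(n + 1), 2:(n + 1)] <- bits
  g
}
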