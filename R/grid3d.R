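# Cartesian grids for the 3D stage

#' Construct a 3D grid specification
#'
#' @param origin Numeric length-3, coordinates of the first grid point
#'   (Angstrom).
#' @param spacing Numeric length-3 (or scalar), grid step per axis (A).
#' @param shape Integer length-3, points per axis.
#' @return Object of class `grid_spec` with `origin`, `spacing`,
#'   `shape`, `n` (total points) and `dv` (voxel volume, A^3).
#' @export
grid_spec <- function(origin, spacing, shape) {
  spacing <- rep(as.numeric(spacing), length.out = 3)
  shape <- as.integer(rep(shape, length.out = 3))
  if (any(spacing <= 0)) stop("spacing must be > 0")
  if (any(shape < 2)) stop("shape must be >= 2 per axis")
  structure(
    list(origin = as.numeric(origin), spacing = spacing, shape = shape,
         n = prod(shape), dv = prod(spacing)),
    class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec>  %d x %d x %d @ (%.3g, %.3g, %.3g) A, origin (%.2f, %.2f, %.2f)\n",
              x$shape[1], x$shape[2], x$shape[3],
              x$spacing[1], x$spacing[2], x$spacing[3],
              x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

#' Next FFT-friendly size
#'
#' Smallest even integer >= `n` whose prime factors are all in
#' {2, 3, 5, 7}.
#'
#' @param n Lower bound.
#' @return Integer.
#' @export
fft_friendly_size <- function(n) {
  n <- max(2L, as.integer(ceiling(n)))
  if (n %% 2L == 1L) n <- n + 1L
  repeat {
    m <- n
    for (p in c(2L, 3L, 5L, 7L)) while (m %% p == 0L) m <- m %/% p
    if (m == 1L) return(n)
    n <- n + 2L
  }
}

#' Build a solvation grid around a solute
#'
#' Axis-aligned box covering the solute's atomic extents plus `buffer`
#' on every side, with the point count per axis rounded up to an
#' FFT-friendly size (even, 7-smooth).  The box is centered on the
#' solute's bounding box.
#'
#' @param solute A [solute_system()].
#' @param buffer Solvation buffer per side, A (> 0).
#' @param spacing Grid spacing, A.
#' @param max_bytes Memory ceiling: an error (reporting the required
#'   bytes) is raised if the solver's working set for this grid would
#'   exceed it.  Default 4 GiB.
#' @return A [grid_spec()].
#' @export
build_grid <- function(solute, buffer = 12, spacing = 0.25,
                       max_bytes = 4 * 1024^3) {
  if (buffer <= 0) stop("buffer must be > 0")
  a <- solute$atoms
  lo <- c(min(a$x), min(a$y), min(a$z)) - buffer
  hi <- c(max(a$x), max(a$y), max(a$z)) + buffer
  shape <- vapply((hi - lo) / spacing + 1, fft_friendly_size, 1L)
  # ~14 double fields of the full grid live at once in the 2-site solver
  need <- prod(shape) * 8 * 14
  if (need > max_bytes)
    stop(sprintf("grid %s exceeds the memory ceiling: needs ~%.0f bytes (> %.0f)",
                 paste(shape, collapse = "x"), need, max_bytes))
  center <- (lo + hi) / 2
  origin <- center - (shape - 1) * spacing / 2
  grid_spec(origin, spacing, shape)
}

#' Grid point coordinates along each axis
#' @keywords internal
grid_axes <- function(grid) {
  lapply(1:3, function(i)
    grid$origin[i] + (seq_len(grid$shape[i]) - 1) * grid$spacing[i])
}

# FFT frequency magnitudes |k| on the reciprocal lattice, plus per-axis
# components (standard wrap-around ordering).
#' @keywords internal
grid_kmag <- function(grid) {
  kax <- lapply(1:3, function(i) {
    n <- grid$shape[i]
    f <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1))
    2 * pi * f / (n * grid$spacing[i])
  })
  nx <- grid$shape[1]; ny <- grid$shape[2]; nz <- grid$shape[3]
  k2 <- array(rep(kax[[1]]^2, times = ny * nz), dim = grid$shape) +
    array(rep(rep(kax[[2]]^2, each = nx), times = nz), dim = grid$shape) +
    array(rep(kax[[3]]^2, each = nx * ny), dim = grid$shape)
  list(kmag = sqrt(k2), kax = kax)
}

# Broadcast per-axis vectors into a full 3D array of squared distances
# to a point (ax, ay, az).
#' @keywords internal
grid_dist2 <- function(axes, shape, p) {
  nx <- shape[1]; ny <- shape[2]; nz <- shape[3]
  dx2 <- (axes[[1]] - p[1])^2
  dy2 <- (axes[[2]] - p[2])^2
  dz2 <- (axes[[3]] - p[3])^2
  array(rep(dx2, times = ny * nz), dim = shape) +
    array(rep(rep(dy2, each = nx), times = nz), dim = shape) +
    array(rep(dz2, each = nx * ny), dim = shape)
}
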