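# Radial grid and fast radial Fourier transforms (type-I DST via FFT)

#' Construct a radial grid
#'
#' Uniform real-space abscissae `r_i = i * dr` (i = 1..n) with the
#' conjugate reciprocal grid `k_j = j * dk`, `dk = pi / ((n + 1) dr)`,
#' the natural grid of the type-I discrete sine transform used for the
#' radial Fourier transforms.  Neither grid contains the origin, which
#' is where the bare Coulomb terms diverge; the k -> 0 physics is
#' carried analytically (Ng splitting).
#'
#' @param n_points Number of radial points (default 2^13).
#' @param dr Radial spacing in Angstrom (default 0.01).
#' @return Object of class `radial_grid` with `r`, `k`, `dr`, `dk`,
#'   `n_points`.
#' @export
radial_grid <- function(n_points = 8192L, dr = 0.01) {
  if (dr <= 0) stop("dr must be > 0")
  n_points <- as.integer(n_points)
  if (n_points < 8L) stop("n_points too small")
  dk <- pi / ((n_points + 1) * dr)
  structure(
    list(n_points = n_points, dr = dr, dk = dk,
         r = seq_len(n_points) * dr, k = seq_len(n_points) * dk),
    class = "radial_grid")
}

# Type-I DST of a vector: S_j = sum_i x_i sin(pi i j / (n+1)),
# computed with one complex FFT of the odd extension.
#' @keywords internal
dst1 <- function(x) {
  n <- length(x)
  v <- c(0, x, 0, -rev(x))
  -Im(stats::fft(v))[2:(n + 1)] / 2
}

#' Radial Fourier transform pair
#'
#' `radial_fft` maps f(r) to `fhat(k) = (4 pi / k) int r f(r) sin(kr) dr`;
#' `radial_ifft` is its inverse on the conjugate grid.
#'
#' @param f Values on `grid$r` (forward) or `grid$k` (inverse).
#' @param grid A [radial_grid()].
#' @return Transformed values on the conjugate grid.
#' @export
radial_fft <- function(f, grid) {
  (4 * pi * grid$dr / grid$k) * dst1(grid$r * f)
}

#' @rdname radial_fft
#' @export
radial_ifft <- function(f, grid) {
  (grid$dk / (2 * pi^2 * grid$r)) * dst1(grid$k * f)
}
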