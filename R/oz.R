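# 3D Ornstein-Zernike convolution: h_b(k) = sum_a m_a c_a(k) chi_ab(k)

#' Interpolate solvent susceptibility onto a 3D reciprocal lattice
#'
#' @param chi A `susceptibility_table` (or compatible list with `k`,
#'   `chi` matrix with `"A:B"` column names, and `site_table`).
#' @param grid A [grid_spec()].
#' @return List: `pairs` (named list of 3D arrays, chi per site-type
#'   pair on |k|), `types`, `mult` (named multiplicities).
#' @keywords internal
chi_on_grid <- function(chi, grid) {
  kmag <- grid_kmag(grid)$kmag
  if (max(kmag) > max(chi$k) + 1e-9)
    stop(sprintf(
      "susceptibility k-range (%.3g 1/A) is shorter than the grid Nyquist (%.3g 1/A)",
      max(chi$k), max(kmag)))
  kv <- as.numeric(kmag)
  pairs <- lapply(colnames(chi$chi), function(nm) {
    array(stats::approx(chi$k, chi$chi[, nm], xout = kv, rule = 2)$y,
          dim = grid$shape)
  })
  names(pairs) <- colnames(chi$chi)
  mult <- chi$site_table$multiplicity
  names(mult) <- chi$site_table$type
  list(pairs = pairs, types = chi$site_table$type, mult = mult)
}

#' @keywords internal
chi_grid_lookup <- function(cg, a, b) {
  p <- cg$pairs[[paste(a, b, sep = ":")]]
  if (is.null(p)) p <- cg$pairs[[paste(b, a, sep = ":")]]
  if (is.null(p)) stop(sprintf("no susceptibility for pair %s:%s", a, b))
  p
}

#' Ornstein-Zernike convolution of 3D direct correlations
#'
#' Computes the total correlation fields
#' `h_b(k) = sum_a m_a c_a(k) chi_ab(k)` by forward/inverse FFT, where
#' `m_a` is the site multiplicity and chi is radially interpolated onto
#' the grid's reciprocal lattice.  Optional analytic long-range parts of
#' c (`cl_k`, complex k-space arrays) are added to the transformed
#' real-space fields before the convolution.
#'
#' @param c_fields Named list (by site type) of real-space direct
#'   correlation arrays sharing one grid.
#' @param chi A `susceptibility_table` (or compatible list).
#' @param grid A [grid_spec()].
#' @param cl_k Optional named list of complex k-space long-range parts.
#' @return Named list of real-space total correlation arrays `h_b`.
#' @export
oz_convolve <- function(c_fields, chi, grid, cl_k = NULL) {
  cg <- chi_on_grid(chi, grid)
  types <- names(c_fields)
  ck <- lapply(types, function(ty) {
    v <- stats::fft(c_fields[[ty]]) * grid$dv
    if (!is.null(cl_k) && !is.null(cl_k[[ty]])) v <- v + cl_k[[ty]]
    v
  })
  names(ck) <- types
  h <- lapply(types, function(tb) {
    hk <- array(0+0i, dim = grid$shape)
    for (ta in types)
      hk <- hk + cg$mult[[ta]] * ck[[ta]] * chi_grid_lookup(cg, ta, tb)
    Re(stats::fft(hk, inverse = TRUE)) / (grid$n * grid$dv)
  })
  names(h) <- types
  h
}
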