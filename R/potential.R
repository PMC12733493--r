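# Solute-site interaction potential on the 3D grid, Ng-split:
#   u = u_short + u_long
#   u_short = sum_atoms [ LJ(sigma_comb, eps_comb) + C q_site q_a erfc(eta r)/r ]
#   u_long  = carried analytically in k-space (Gaussian-screened Coulomb)

#' Build the solute-solvent-site potential field
#'
#' Lorentz-Berthelot combining (arithmetic sigma, geometric epsilon) for
#' the solute-site LJ cross terms; Coulomb split with `erfc`/`erf`
#' damping so the short-range part decays fast in real space and the
#' long-range part has an analytic Gaussian-screened k-space form.  The
#' k = 0 Coulomb mode is dropped, which for a net-charged solute is
#' equivalent to a uniform neutralizing background.
#'
#' @param solute A [solute_system()].
#' @param site One row of a solvent site table (list/row with `charge`,
#'   `sigma`, `epsilon`).
#' @param grid A [grid_spec()].
#' @param eta Coulomb splitting parameter, 1/A.  Default 0.5.
#' @param core_cap Cap on `u_short/kT` inside hard cores (default 40);
#'   guarantees finite fields (`exp(-core_cap)` underflows gracefully in
#'   the closure).
#' @param temperature K, used to express the field in kT units.
#' @return Object of class `potential_field`: `u_short` (3D array, kT
#'   units, capped at `core_cap`), `u_long_k` (complex 3D array, the
#'   k-space long-range part in kT A^3), `beta` (mol/kcal bookkeeping),
#'   `eta`, `grid`.
#' @export
build_potential <- function(solute, site, grid, eta = 0.5, core_cap = 40,
                            temperature = 298.15) {
  a <- solute$atoms
  beta <- 1 / kT_kcal(temperature)
  axes <- grid_axes(grid)
  u <- array(0, dim = grid$shape)
  rmin <- min(grid$spacing) / 20   # floor against exact atom-center hits
  for (i in seq_len(nrow(a))) {
    r <- sqrt(grid_dist2(axes, grid$shape, c(a$x[i], a$y[i], a$z[i])))
    r[r < rmin] <- rmin
    sig <- (a$sigma[i] + site$sigma) / 2
    eps <- sqrt(a$epsilon[i] * site$epsilon)
    if (sig > 0 && eps > 0) {
      sr6 <- (sig / r)^6
      u <- u + 4 * eps * (sr6 * sr6 - sr6)
    }
    qq <- site$charge * a$charge[i]
    if (qq != 0)
      u <- u + COULOMB_KCAL * qq * erfc_(eta * r) / r
  }
  u_short <- pmin(beta * u, core_cap)

  kk <- grid_kmag(grid)
  kmag <- kk$kmag
  ulk <- array(0+0i, dim = grid$shape)
  if (site$charge != 0 && any(a$charge != 0)) {
    nx <- grid$shape[1]; ny <- grid$shape[2]; nz <- grid$shape[3]
    for (i in seq_len(nrow(a))) {
      if (a$charge[i] == 0) next
      px <- exp(-1i * kk$kax[[1]] * (a$x[i] - grid$origin[1]))
      py <- exp(-1i * kk$kax[[2]] * (a$y[i] - grid$origin[2]))
      pz <- exp(-1i * kk$kax[[3]] * (a$z[i] - grid$origin[3]))
      ph <- array(rep(px, times = ny * nz), dim = grid$shape) *
        array(rep(rep(py, each = nx), times = nz), dim = grid$shape) *
        array(rep(pz, each = nx * ny), dim = grid$shape)
      ulk <- ulk + a$charge[i] * ph
    }
    kern <- beta * COULOMB_KCAL * site$charge * 4 * pi *
      exp(-kmag^2 / (4 * eta^2)) / pmax(kmag, 1e-12)^2
    kern[1, 1, 1] <- 0   # neutralizing background
    ulk <- ulk * kern
  }
  structure(
    list(u_short = u_short, u_long_k = ulk, beta = beta, eta = eta,
         core_cap = core_cap, grid = grid),
    class = "potential_field")
}

#' Reconstruct the real-space long-range potential
#'
#' Inverse FFT of `u_long_k`; used for validation against direct
#' pairwise summation (the reconstruction carries the periodic images
#' implied by the FFT, so agreement requires an adequately buffered box).
#'
#' @param pot A [build_potential()] result.
#' @return 3D array, kT units.
#' @export
u_long_real <- function(pot) {
  g <- pot$grid
  Re(stats::fft(pot$u_long_k, inverse = TRUE)) / (g$n * g$dv)
}
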