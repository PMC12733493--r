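# Closure relations (Kovalenko-Hirata and HNC), shared by the 1D and 3D stages

#' Apply a closure relation
#'
#' Given the closure argument `d = -u/kT + h - c` (the "renormalized
#' indirect correlation"), return the distribution function g.
#'
#' * `"kh"` (Kovalenko-Hirata): `g = exp(d)` where `d <= 0` (depletion),
#'   `g = 1 + d` where `d > 0` (enhancement).  The two branches meet at
#'   `d = 0` with matching value (1) and slope (1), and g is
#'   non-negative by construction.
#' * `"hnc"`: `g = exp(d)` everywhere.
#'
#' @param d Numeric vector/array of closure arguments (dimensionless).
#' @param closure `"kh"` or `"hnc"`.
#' @return g, same shape as `d`.
#' @export
closure_g <- function(d, closure = c("kh", "hnc")) {
  closure <- match.arg(closure)
  if (closure == "hnc") return(exp(d))
  g <- exp(pmin(d, 0))
  up <- d > 0
  g[up] <- 1 + d[up]
  g
}

#' Kovalenko-Hirata closure update
#'
#' One closure half-step of the coupled OZ/closure iteration, in the
#' Ng-renormalized variables: given the short-range potential
#' `u_short/kT` and the renormalized indirect correlation
#' `tstar = h - c_short`, returns `g` and the new short-range direct
#' correlation `c_short = g - 1 - tstar`.
#'
#' @param u_short_kT Short-range potential in kT units (long-range
#'   Coulomb already split off analytically).
#' @param tstar Renormalized indirect correlation function.
#' @param closure `"kh"` or `"hnc"`.
#' @return List with `g` and `c_short` (same shapes as the inputs).
#' @export
kh_closure <- function(u_short_kT, tstar, closure = "kh") {
  d <- tstar - u_short_kT
  g <- closure_g(d, closure)
  list(g = g, c_short = g - 1 - tstar)
}
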