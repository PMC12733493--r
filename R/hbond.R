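# Fraction of first-shell water hydrogen-bonded to the solute.
#
# Geometric criterion on the converged density fields: water hydrogens
# concentrated within r_acceptor of a solute N/O acceptor donate a bond
# to the solute; water oxygens within r_donor of a solute donor heavy
# atom (N/O carrying a bonded hydrogen) accept one.

#' Classify solute polar atoms
#'
#' Acceptors: N and O atoms (optionally S).  Donor heavy atoms: N/O
#' with at least one hydrogen within `bond_max`.
#'
#' @param solute A [solute_system()].
#' @param bond_max Covalent X-H bond cutoff, A (default 1.25).
#' @param acceptor_elements Elements counted as acceptors.
#' @return List of row-index vectors `acceptors`, `donors`.
#' @export
classify_polar_atoms <- function(solute, bond_max = 1.25,
                                 acceptor_elements = c("N", "O")) {
  a <- solute$atoms
  acc <- which(a$element %in% acceptor_elements)
  hyd <- which(a$element == "H")
  don <- integer(0)
  if (length(hyd) && length(acc)) {
    hp <- cbind(a$x[hyd], a$y[hyd], a$z[hyd])
    for (i in acc) {
      d2 <- (hp[, 1] - a$x[i])^2 + (hp[, 2] - a$y[i])^2 + (hp[, 3] - a$z[i])^2
      if (any(d2 <= bond_max^2)) don <- c(don, i)
    }
  }
  list(acceptors = acc, donors = don)
}

#' @keywords internal
min_dist_field <- function(positions, grid) {
  axes <- grid_axes(grid)
  d2 <- array(Inf, dim = grid$shape)
  for (i in seq_len(nrow(positions))) {
    r2 <- grid_dist2(axes, grid$shape, positions[i, ])
    d2 <- pmin(d2, r2)
  }
  sqrt(d2)
}

#' Fraction of shell water H-bonded to the solute
#'
#' The H-bonded count is the rho_Hw-weighted integral of g_Hw over the
#' union of spheres of radius `r_acceptor` around solute N/O acceptors,
#' plus the rho_Ow-weighted integral of g_Ow over spheres of radius
#' `r_donor` around solute donor heavy atoms.  The fraction is this
#' count divided by the total hydration number for the same `r_cut`,
#' clamped to [0, 1] with a warning if clamping was needed.
#'
#' @param g_Hw,g_Ow Converged distribution arrays.
#' @param solute A [solute_system()].
#' @param dist A [distance_transform()] result (for the total count).
#' @param r_cut Shell boundary, A.
#' @param rho_mol Molecular bulk density, 1/A^3 (hydrogen site density
#'   is twice this).
#' @param criterion List: `r_acceptor` (A, default 2.6), `r_donor` (A,
#'   default 3.5), `bond_max` (default 1.25).
#' @return Scalar fraction in [0, 1]; attribute `"count"` carries the
#'   raw H-bonded water estimate.
#' @export
hbond_fraction <- function(g_Hw, g_Ow, solute, dist, r_cut, rho_mol,
                           criterion = list()) {
  cr <- utils::modifyList(
    list(r_acceptor = 2.6, r_donor = 3.5, bond_max = 1.25), criterion)
  grid <- dist$grid
  pol <- classify_polar_atoms(solute, bond_max = cr$bond_max)
  n_tot <- hydration_number(g_Ow, dist, r_cut, rho_mol)
  if (!length(pol$acceptors) && !length(pol$donors)) {
    message("solute has no polar atoms: H-bond fraction is 0")
    return(structure(0, count = 0, n_tot = n_tot))
  }
  a <- solute$atoms
  count <- 0
  if (length(pol$acceptors)) {
    da <- min_dist_field(cbind(a$x, a$y, a$z)[pol$acceptors, , drop = FALSE],
                         grid)
    count <- count + 2 * rho_mol * grid$dv * sum(g_Hw[da <= cr$r_acceptor])
  }
  if (length(pol$donors)) {
    dd <- min_dist_field(cbind(a$x, a$y, a$z)[pol$donors, , drop = FALSE],
                         grid)
    count <- count + rho_mol * grid$dv * sum(g_Ow[dd <= cr$r_donor])
  }
  frac <- if (n_tot > 0) count / n_tot else 0
  if (frac > 1) {
    warning(sprintf("H-bond fraction %.3f clamped to 1", frac))
    frac <- 1
  }
  structure(frac, count = count, n_tot = n_tot)
}
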