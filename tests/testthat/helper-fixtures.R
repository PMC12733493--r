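# Shared fixtures for the suite.  Expensive solvent solves are memoized
# per session.

.fixture_cache <- new.env(parent = emptyenv())

# Converged MSPC/E water susceptibility at production quality
# (2^13 points, dr = 0.01 A); ~10 s, shared across tests.
water_chi <- function() {
  if (is.null(.fixture_cache$chi)) {
    m <- solvent_catalogue("mspce")
    .fixture_cache$chi <- solve_rism1d(m, radial_grid(8192L, 0.01),
                                       closure = "kh")
  }
  .fixture_cache$chi
}

# Coarser water susceptibility for fast 3D smoke solves
# (2^12 points, dr = 0.02 A).
water_chi_fast <- function() {
  if (is.null(.fixture_cache$chi_fast)) {
    m <- solvent_catalogue("mspce")
    .fixture_cache$chi_fast <- solve_rism1d(m, radial_grid(4096L, 0.02),
                                            closure = "kh")
  }
  .fixture_cache$chi_fast
}

# Converged LJ-sphere solve on the 64^3 / 0.5 A reference box, shared
# between solver and acceptance tests.
lj_reference_solve <- function() {
  if (is.null(.fixture_cache$ljref)) {
    sol <- make_toy_solute(fixture_recipe("lj_sphere"))
    grid <- grid_spec(origin = rep(-63 * 0.5 / 2, 3), spacing = 0.5,
                      shape = 64L)
    .fixture_cache$ljref <- list(
      solute = sol, grid = grid,
      fields = solve_rism3d(sol, water_chi(), grid = grid, tol = 1e-6,
                            max_iter = 300L))
  }
  .fixture_cache$ljref
}

# A minimal neutral "water-like" model with all interactions off, for
# ideal-gas limits.
noninteracting_water <- function() {
  solvent_model(list(
    solvent_site("Ow", 0, 0, 0, c(0, 0, 0)),
    solvent_site("Hw", 0, 0, 0, c(0.8164966, 0.5773503, 0)),
    solvent_site("Hw", 0, 0, 0, c(-0.8164966, 0.5773503, 0))),
    density = 0.03332, temperature = 298.15, name = "ideal")
}

# Synthetic susceptibility acting as the identity kernel for one site
# type: chi == 1 for all k (omega = 1, no solvent correlations).
identity_chi <- function(kmax = 1000) {
  k <- seq(0.001, kmax, length.out = 64)
  chi <- matrix(1, length(k), 1, dimnames = list(NULL, "X:X"))
  list(k = k, chi = chi,
       site_table = data.frame(type = "X", multiplicity = 1L,
                               charge = 0, sigma = 0, epsilon = 0,
                               rho_site = 0.0334))
}

# Two-Gaussian shell profile used in several quadrature tests.
shell_gfun <- function(d) {
  1 + 1.5 * exp(-(d - 2.8)^2 / 0.18) - 0.4 * exp(-(d - 4.0)^2 / 0.32)
}
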