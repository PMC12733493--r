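# Synthetic fixtures: toy parameterized solutes, painted analytic
# density fields, and randomized shell profiles with known extrema.
# Every fixture is reproducible from (recipe, seed).

#' Define a fixture recipe
#'
#' @param kind One of `"lj_sphere"`, `"ion"`, `"rigid_water_solute"`,
#'   `"polyatomic_random"`.
#' @param ... Per-kind numeric parameters (see [make_toy_solute()]).
#' @param seed RNG seed for randomized kinds.
#' @return Object of class `fixture_recipe`.
#' @export
fixture_recipe <- function(kind = c("lj_sphere", "ion",
                                    "rigid_water_solute",
                                    "polyatomic_random"),
                           ..., seed = 1L) {
  kind <- match.arg(kind)
  structure(list(kind = kind, params = list(...), seed = as.integer(seed)),
            class = "fixture_recipe")
}

#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", .GlobalEnv)) rm(".Random.seed", envir = .GlobalEnv)
    } else assign(".Random.seed", old, envir = .GlobalEnv)
  })
  set.seed(seed)
  force(expr)
}

#' Build a toy parameterized solute
#'
#' Recipe kinds and their parameters (defaults in parentheses):
#' * `lj_sphere`: one neutral LJ atom at the origin; `sigma` (3.15 A),
#'   `epsilon` (0.15 kcal/mol), `q` (0).
#' * `ion`: one charged LJ atom; `q` (-1), `sigma` (4.4), `epsilon`
#'   (0.1).
#' * `rigid_water_solute`: a single SPC/E-geometry water treated as the
#'   solute.
#' * `polyatomic_random`: `n` (10) atoms uniform in a sphere of radius
#'   `R` (4 A), random LJ parameters, charges recentred to exactly zero
#'   net charge; one residue per atom, so residue partitions are
#'   non-trivial.
#'
#' @param recipe A [fixture_recipe()].
#' @return A [solute_system()].
#' @export
make_toy_solute <- function(recipe) {
  stopifnot(inherits(recipe, "fixture_recipe"))
  p <- recipe$params
  dflt <- function(name, val) if (is.null(p[[name]])) val else p[[name]]
  mk <- function(x, y, z, q, sig, eps, name = "X", elem = "X",
                 resid = "TOY", resno = 1L) {
    if (any(sig < 0)) stop("recipe error: negative sigma")
    if (any(eps < 0)) stop("recipe error: negative epsilon")
    data.frame(serial = seq_along(x), name = name, element = elem,
               resid = resid, resno = resno, chain = "A",
               x = x, y = y, z = z, charge = q, sigma = sig,
               epsilon = eps, radius = ifelse(sig > 0, sig * 2^(1 / 6) / 2, 1.0),
               stringsAsFactors = FALSE)
  }
  atoms <- switch(
    recipe$kind,
    lj_sphere = mk(0, 0, 0, dflt("q", 0), dflt("sigma", 3.15),
                   dflt("epsilon", 0.15), name = "LJ", elem = "C",
                   resid = "LJS"),
    ion = mk(0, 0, 0, dflt("q", -1), dflt("sigma", 4.4),
             dflt("epsilon", 0.1), name = "ION", elem = "CL",
             resid = "ION"),
    rigid_water_solute = mk(
      x = c(0, 0.8164966, -0.8164966), y = c(0, 0.5773503, 0.5773503),
      z = c(0, 0, 0), q = c(-0.8476, 0.4238, 0.4238),
      sig = c(3.166, 1.0, 1.0), eps = c(0.1553, 0.0545, 0.0545),
      name = c("O", "H1", "H2"), elem = c("O", "H", "H"),
      resid = "HOH", resno = 1L),
    polyatomic_random = with_seed(recipe$seed, {
      n <- dflt("n", 10L); R <- dflt("R", 4)
      if (R <= 0) stop("recipe error: negative radius")
      # uniform in a sphere via rejection
      pts <- matrix(NA_real_, 0, 3)
      while (nrow(pts) < n) {
        cand <- matrix(stats::runif(3 * n, -R, R), ncol = 3)
        cand <- cand[rowSums(cand^2) <= R^2, , drop = FALSE]
        pts <- rbind(pts, cand)
      }
      pts <- pts[seq_len(n), , drop = FALSE]
      q <- stats::rnorm(n, 0, 0.3)
      q <- q - mean(q)          # zero net charge by construction
      mk(pts[, 1], pts[, 2], pts[, 3], q,
         stats::runif(n, 2.6, 3.6), stats::runif(n, 0.05, 0.2),
         name = sprintf("X%d", seq_len(n)), elem = "C",
         resid = "TOY", resno = seq_len(n))
    }))
  solute_system(atoms,
                provenance = list(fixture = recipe$kind,
                                  seed = recipe$seed,
                                  params = recipe$params))
}

#' Paint a radial profile onto a 3D grid
#'
#' Field value at each voxel is `profile(d)` where d is the same
#' distance-to-solute the analysis stage uses, so integrals of painted
#' fields have known 1D quadrature values.
#'
#' @param profile Function of distance (A); must return finite values
#'   over the grid's distance range.
#' @param solute A [solute_system()].
#' @param grid A [grid_spec()].
#' @param dist Optional precomputed [distance_transform()].
#' @return 3D array.
#' @export
paint_radial_field <- function(profile, solute, grid, dist = NULL) {
  if (is.null(dist)) dist <- distance_transform(solute, grid)
  v <- profile(as.numeric(dist$d))
  if (any(!is.finite(v)))
    stop("profile undefined (non-finite) within the grid's distance range")
  array(v, dim = grid$shape)
}

#' Random shell profile with known extrema
#'
#' A two-Gaussian shell-density profile
#' `s(r) = 1 + A exp(-(r - p)^2 / 2 wp^2) - B exp(-(r - t)^2 / 2 wt^2)`
#' with randomized peak/trough positions, amplitudes and widths, plus
#' the analytic extrema of the constructed function (located on the
#' smooth curve itself, independent of any binning).
#'
#' @param seed RNG seed.
#' @param ranges List overriding the sampling ranges: `peak_pos`,
#'   `peak_amp`, `peak_w`, `sep` (trough offset), `trough_amp`,
#'   `trough_w`, each `c(lo, hi)`.
#' @param bin Sampling bin for the returned profile, A.
#' @param r_max Profile range, A.
#' @return List: `profile` (a `shell_profile`), `fun`, `true_peak`,
#'   `true_trough`, `params`.
#' @export
make_shell_profile <- function(seed = 1L, ranges = list(), bin = 0.1,
                               r_max = 10) {
  rg <- utils::modifyList(
    list(peak_pos = c(2.4, 3.2), peak_amp = c(0.6, 2.0),
         peak_w = c(0.25, 0.45), sep = c(0.9, 1.6),
         trough_amp = c(0.1, 0.5), trough_w = c(0.3, 0.6)), ranges)
  bad <- vapply(rg[c("peak_amp", "trough_amp")], function(v) any(v < 0), TRUE)
  if (any(bad)) stop("profile ranges invalid: negative amplitude")
  pars <- with_seed(seed, list(
    p = stats::runif(1, rg$peak_pos[1], rg$peak_pos[2]),
    A = stats::runif(1, rg$peak_amp[1], rg$peak_amp[2]),
    wp = stats::runif(1, rg$peak_w[1], rg$peak_w[2]),
    sep = stats::runif(1, rg$sep[1], rg$sep[2]),
    B = stats::runif(1, rg$trough_amp[1], rg$trough_amp[2]),
    wt = stats::runif(1, rg$trough_w[1], rg$trough_w[2])))
  pars$t <- pars$p + pars$sep
  fun <- function(r)
    1 + pars$A * exp(-(r - pars$p)^2 / (2 * pars$wp^2)) -
      pars$B * exp(-(r - pars$t)^2 / (2 * pars$wt^2))
  pk <- stats::optimize(fun, c(max(0, pars$p - 1), pars$p + 1),
                        maximum = TRUE)
  tr <- stats::optimize(fun, c(pars$p, pars$t + 2 * pars$wt))
  r <- seq(bin, r_max, by = bin)
  list(profile = as_shell_profile(r, fun(r)),
       fun = fun, true_peak = pk$maximum, true_trough = tr$minimum,
       params = pars)
}
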