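# 3D-RISM solver: fixed point of (OZ convolution o closure) by MDIIS

#' Solve the 3D-RISM equations for a solute in a precomputed solvent
#'
#' Iterates the 3D Ornstein-Zernike equation together with the
#' Kovalenko-Hirata (or HNC) closure to a fixed point in the short-range
#' direct correlation functions, one field per distinct solvent site
#' type.  Long-range electrostatics are Ng-split: the Gaussian-screened
#' Coulomb part of c is carried analytically in k-space, and the
#' iteration starts from `c = -u_long` (short-range part zero), which
#' removes the dominant slow mode.
#'
#' @param solute A [solute_system()].
#' @param solvent A `susceptibility_table` from [solve_rism1d()] (or
#'   [read_susceptibility()]).
#' @param grid A [grid_spec()], or `NULL` to build one from `buffer` and
#'   `spacing`.
#' @param buffer,spacing Passed to [build_grid()] when `grid` is `NULL`.
#' @param closure `"kh"` or `"hnc"`.
#' @param tol Max-norm residual tolerance on c_short (default 1e-6).
#' @param max_iter Iteration cap (default 500).
#' @param n_vectors MDIIS subspace size (default 5; 1 = damped Picard).
#' @param damp Mixing parameter (default 0.7).
#' @param eta Coulomb splitting parameter, 1/A (default 0.5).
#' @param core_cap Cap on u_short/kT (default 40).
#' @param initial `"ulong"` (c_short = 0, the default) or a named list
#'   of starting c_short arrays.
#' @return Object of class `solvation_fields`: per site type the arrays
#'   `g`, `h`, `c_short`; plus `grid`, `site_types`, `multiplicities`,
#'   `rho_site`, `residual`, `trace`, `iterations`, `converged`,
#'   `params` (all solver settings, for provenance).
#' @export
solve_rism3d <- function(solute, solvent, grid = NULL, buffer = 12,
                         spacing = 0.25, closure = c("kh", "hnc"),
                         tol = 1e-6, max_iter = 500L, n_vectors = 5L,
                         damp = 0.7, eta = 0.5, core_cap = 40,
                         initial = "ulong") {
  closure <- match.arg(closure)
  if (is.null(grid)) grid <- build_grid(solute, buffer = buffer,
                                        spacing = spacing)
  st <- solvent$site_table
  types <- st$type
  nt <- length(types)
  temperature <- solvent$temperature

  pots <- lapply(seq_len(nt), function(i)
    build_potential(solute, st[i, ], grid, eta = eta,
                    core_cap = core_cap, temperature = temperature))
  names(pots) <- types
  cl_k <- lapply(pots, function(p) -p$u_long_k)

  cg <- chi_on_grid(solvent, grid)
  mult <- cg$mult

  npt <- grid$n
  idx <- function(i) ((i - 1) * npt + 1):(i * npt)
  last <- new.env(parent = emptyenv())

  residual_fun <- function(x) {
    ck <- vector("list", nt); names(ck) <- types
    csk <- vector("list", nt); names(csk) <- types
    for (i in seq_len(nt)) {
      cs <- array(x[idx(i)], dim = grid$shape)
      csk[[i]] <- stats::fft(cs) * grid$dv
      ck[[i]] <- csk[[i]] + cl_k[[i]]
    }
    out <- numeric(length(x))
    gs <- vector("list", nt); names(gs) <- types
    hs <- vector("list", nt); names(hs) <- types
    for (i in seq_len(nt)) {
      tb <- types[i]
      hk <- array(0+0i, dim = grid$shape)
      for (j in seq_len(nt))
        hk <- hk + mult[[types[j]]] * ck[[j]] * chi_grid_lookup(cg, types[j], tb)
      tstar_k <- hk - csk[[i]]
      tstar <- Re(stats::fft(tstar_k, inverse = TRUE)) / (npt * grid$dv)
      upd <- kh_closure(pots[[i]]$u_short, tstar, closure)
      gs[[i]] <- upd$g
      hs[[i]] <- upd$g - 1
      out[idx(i)] <- as.numeric(upd$c_short) - x[idx(i)]
    }
    last$g <- gs; last$h <- hs
    out
  }

  x0 <- if (is.list(initial)) {
    unlist(lapply(types, function(ty) as.numeric(initial[[ty]])))
  } else rep(0, nt * npt)

  sol <- mdiis_solve(x0, residual_fun, n_vectors = n_vectors, tol = tol,
                     max_iter = max_iter, damp = damp)
  invisible(residual_fun(sol$x))

  cshort <- lapply(seq_len(nt), function(i) array(sol$x[idx(i)], dim = grid$shape))
  names(cshort) <- types
  rho_site <- st$rho_site; names(rho_site) <- types

  structure(
    list(grid = grid, site_types = types,
         multiplicities = mult, rho_site = rho_site,
         g = last$g, h = last$h, c_short = cshort,
         residual = sol$residual, trace = sol$trace,
         iterations = sol$iterations, converged = sol$converged,
         params = list(closure = closure, tol = tol,
                       n_vectors = n_vectors, damp = damp, eta = eta,
                       core_cap = core_cap, spacing = grid$spacing,
                       buffer = buffer, temperature = temperature,
                       solvent = solvent$model_name,
                       density = solvent$density)),
    class = "solvation_fields")
}

#' @export
print.solvation_fields <- function(x, ...) {
  cat(sprintf("<solvation_fields>  sites %s on %s grid\n",
              paste(x$site_types, collapse = ", "),
              paste(x$grid$shape, collapse = "x")))
  cat(sprintf("  %s closure, residual %.3e after %d iterations (%s)\n",
              toupper(x$params$closure), x$residual, x$iterations,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Mean deviation of g from 1 on the outermost grid shell
#'
#' Diagnostic for box adequacy: for a well-buffered box the solvent is
#' bulk-like at the boundary and this is small (< 1e-2).
#'
#' @param fields A `solvation_fields` object.
#' @param site Site type (default first).
#' @return Mean of `|g - 1|` over the outermost layer of grid points.
#' @export
boundary_deviation <- function(fields, site = fields$site_types[1]) {
  g <- fields$g[[site]]
  d <- dim(g)
  mask <- array(FALSE, dim = d)
  mask[c(1, d[1]), , ] <- TRUE
  mask[, c(1, d[2]), ] <- TRUE
  mask[, , c(1, d[3])] <- TRUE
  mean(abs(g[mask] - 1))
}

#' Radial average of a 3D field about a center
#'
#' Bins voxels by distance to `center` and averages; used to extract
#' g(r) profiles from single-atom solves and to quantify angular
#' anisotropy (the residual of voxel values around the interpolated
#' radial profile).
#'
#' @param field 3D array.
#' @param grid A [grid_spec()].
#' @param center Numeric length-3 (A).
#' @param dr Radial bin width (default: half the max spacing).
#' @param r_max Maximum radius (default: half the smallest box edge).
#' @return List: `r` (bin centers), `mean`, `n` (voxels per bin),
#'   `asymmetry` (sd of voxel residuals about the interpolated radial
#'   profile divided by the profile's range).
#' @export
radial_average <- function(field, grid, center = c(0, 0, 0), dr = NULL,
                           r_max = NULL) {
  if (is.null(dr)) dr <- max(grid$spacing) / 2
  axes <- grid_axes(grid)
  r <- sqrt(grid_dist2(axes, grid$shape, center))
  if (is.null(r_max)) r_max <- min(grid$shape * grid$spacing) / 2
  sel <- r <= r_max
  rv <- r[sel]; fv <- field[sel]
  ib <- pmin(floor(rv / dr) + 1L, ceiling(r_max / dr))
  nb <- max(ib)
  m <- rowsum_safe(fv, ib, nb) / pmax(rowsum_safe(rep(1, length(ib)), ib, nb), 1)
  centers <- (seq_len(nb) - 0.5) * dr
  ok <- rowsum_safe(rep(1, length(ib)), ib, nb) > 0
  prof <- stats::approx(centers[ok], m[ok], xout = rv, rule = 2)$y
  asym <- stats::sd(fv - prof) / diff(range(m[ok]))
  list(r = centers, mean = m, n = rowsum_safe(rep(1, length(ib)), ib, nb),
       asymmetry = asym)
}
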