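# Hydration-shell profile, boundary criterion and hydration numbers.
#
# The cumulative water count within distance r_cut of the solute is
#   n(r_cut) = rho_Ow * integral over V(r_cut) of g_Ow(r) dr,
# and its derivative n'(r_cut) is the basis of the shell-boundary
# criterion: the first hydration shell shows an increased solvent
# density inside and a reduced one at its boundary, so the first
# minimum of the shell-normalized density after its first peak marks
# the shell thickness.

#' Cumulative shell profile of a solvent distribution
#'
#' Bins grid points by distance to the solute and accumulates the
#' density-weighted integral of g.  `n` is the cumulative molecule
#' count at the right edge of each bin; `n_prime` is its central
#' finite difference; `shell_density` is `n_prime` normalized by the
#' measured shell volume per unit thickness (voxel count per bin times
#' voxel volume), so a bulk field (g = 1) gives exactly 1 and
#' box-shape artifacts cancel.
#'
#' @param g 3D array of the solvent-site distribution function.
#' @param dist A [distance_transform()] result on the same grid.
#' @param rho Bulk site number density, 1/A^3.
#' @param bin Bin width, A; must be >= the largest grid spacing (a
#'   finer bin would alias the derivative).
#' @param r_max Optional profile range cap, A.
#' @param smooth Apply 5-point running-mean smoothing to
#'   `shell_density` (default FALSE).
#' @return Object of class `shell_profile`: `r` (bin right edges),
#'   `n`, `n_prime`, `shell_density`, `counts` (voxels per bin),
#'   `rho`, `bin`.
#' @export
shell_profile <- function(g, dist, rho, bin = NULL, r_max = NULL,
                          smooth = FALSE) {
  grid <- dist$grid
  if (!all(dim(g) == grid$shape)) stop("field and distance grid differ")
  if (is.null(bin)) bin <- max(grid$spacing)
  if (bin < max(grid$spacing) - 1e-9)
    stop(sprintf("bin (%.3g A) below grid spacing (%.3g A): derivative would alias",
                 bin, max(grid$spacing)))
  d <- as.numeric(dist$d)
  gv <- as.numeric(g)
  if (is.null(r_max)) {
    # interior-supported range: beyond the largest inscribed distance the
    # shells are clipped by the box, but the volume normalization still
    # holds; cap at the max distance present
    r_max <- max(d)
  }
  nb <- ceiling(r_max / bin)
  edges <- (0:nb) * bin
  # right-closed bins: a voxel at exactly d = j*bin belongs to bin j, so
  # n at an edge matches the `d <= r_cut` convention of hydration_number
  ib <- pmin(pmax(ceiling(d / bin), 1L), nb)
  mass <- rowsum_safe(gv, ib, nb) * grid$dv * rho
  counts <- rowsum_safe(rep(1, length(ib)), ib, nb)
  n <- c(0, cumsum(mass))              # at edges 0..nb
  vol <- c(0, cumsum(counts)) * grid$dv
  r <- edges
  n_prime <- rep(NA_real_, nb + 1)
  shell_density <- rep(NA_real_, nb + 1)
  if (nb >= 2) {
    j <- 2:nb
    n_prime[j] <- (n[j + 1] - n[j - 1]) / (2 * bin)
    dvdr <- (vol[j + 1] - vol[j - 1]) / (2 * bin)
    shell_density[j] <- ifelse(dvdr > 0, n_prime[j] / (rho * dvdr), NA_real_)
  }
  if (smooth) {
    s <- shell_density
    ok <- which(!is.na(s))
    if (length(ok) >= 5)
      s[ok] <- stats::filter(s[ok], rep(1 / 5, 5), sides = 2) |>
        (\(v) ifelse(is.na(v), s[ok], v))()
    shell_density <- s
  }
  structure(list(r = r, n = n, n_prime = n_prime,
                 shell_density = shell_density, counts = counts,
                 rho = rho, bin = bin),
            class = "shell_profile")
}

#' @keywords internal
rowsum_safe <- function(x, idx, n) {
  out <- numeric(n)
  s <- rowsum(x, idx)
  out[as.integer(rownames(s))] <- s[, 1]
  out
}

#' Construct a shell profile from raw vectors
#'
#' For synthetic profiles with known extrema (see
#' [make_shell_profile()]) and for testing the boundary finder.
#'
#' @param r Abscissae, A.
#' @param shell_density Shell-normalized density values.
#' @param rho Bulk density bookkeeping (default NA).
#' @return A `shell_profile`.
#' @export
as_shell_profile <- function(r, shell_density, rho = NA_real_) {
  stopifnot(length(r) == length(shell_density))
  structure(list(r = r, n = NULL, n_prime = NULL,
                 shell_density = shell_density, counts = NULL,
                 rho = rho, bin = if (length(r) > 1) r[2] - r[1] else NA_real_),
            class = "shell_profile")
}

#' @keywords internal
rismhydra_no_boundary <- function(msg) {
  structure(class = c("rismhydra_no_boundary", "error", "condition"),
            list(message = msg, call = sys.call(-1)))
}

#' Locate the hydration-shell boundary
#'
#' Returns the position of the first local minimum of the
#' shell-normalized density after its first local maximum above 1
#' (bulk), refined by a parabolic fit through the three bracketing
#' bins.  A profile with no peak above bulk or no following minimum is
#' bulk-like and raises a `rismhydra_no_boundary` error.
#'
#' @param profile A `shell_profile`.
#' @return List: `r_cut` (A), `value` (shell density at the minimum),
#'   `weak` (TRUE when the minimum does not dip below bulk density),
#'   `index` (bin index of the minimum).
#' @export
find_shell_boundary <- function(profile) {
  s <- profile$shell_density
  r <- profile$r
  ok <- which(!is.na(s))
  if (length(ok) < 3)
    stop(rismhydra_no_boundary("profile has fewer than 3 usable bins"))
  s <- s[ok]; r <- r[ok]
  m <- length(s)
  peak <- NA_integer_
  for (i in 2:(m - 1)) {
    if (s[i] > 1 && s[i] >= s[i - 1] && s[i] > s[i + 1]) { peak <- i; break }
  }
  if (is.na(peak))
    stop(rismhydra_no_boundary("no shell peak above bulk density: bulk-like solvent"))
  trough <- NA_integer_
  i <- peak + 1L
  while (i <= m - 1) {
    if (s[i] <= s[i - 1] && s[i] < s[i + 1]) { trough <- i; break }
    i <- i + 1L
  }
  if (is.na(trough))
    stop(rismhydra_no_boundary("no density minimum after the shell peak"))
  # parabolic refinement
  sm <- s[trough - 1]; s0 <- s[trough]; sp <- s[trough + 1]
  denom <- sm - 2 * s0 + sp
  h <- r[trough] - r[trough - 1]
  dr <- if (abs(denom) > 1e-14) 0.5 * h * (sm - sp) / denom else 0
  dr <- max(min(dr, h), -h)
  list(r_cut = r[trough] + dr, value = s0, weak = s0 >= 1, index = trough)
}

#' Total hydration number
#'
#' Density-weighted integral of the solvent-site distribution over the
#' first hydration shell `d <= r_cut`.
#'
#' @param g 3D distribution array (typically water oxygen).
#' @param dist A [distance_transform()] result.
#' @param r_cut Shell boundary, A (from [find_shell_boundary()] or
#'   user-supplied).
#' @param rho Bulk site density, 1/A^3.
#' @return Expected molecule count in the shell.
#' @export
hydration_number <- function(g, dist, r_cut, rho) {
  if (r_cut > max(dist$d))
    stop(sprintf("r_cut = %.3g A exceeds the distance-field range (%.3g A)",
                 r_cut, max(dist$d)))
  sum(g[dist$d <= r_cut]) * dist$grid$dv * rho
}
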