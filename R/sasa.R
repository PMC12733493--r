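# Solvent-accessible surface area (Shrake-Rupley with a deterministic
# spherical point set)

#' Deterministic unit-sphere point set (Fibonacci spiral)
#'
#' @param n Number of points.
#' @return n x 3 matrix of unit vectors.
#' @export
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 1
  z <- 1 - (2 * i + 1) / n
  phi <- i * pi * (3 - sqrt(5))
  rho <- sqrt(pmax(0, 1 - z^2))
  cbind(rho * cos(phi), rho * sin(phi), z)
}

#' Bondi-style van der Waals radii
#'
#' Default per-element radii (A) used when a structure carries no
#' radii of its own.
#'
#' @return Named numeric vector.
#' @export
vdw_radii_table <- function() {
  r <- c(1.20, 1.70, 1.55, 1.52, 1.80, 1.80, 1.47, 1.75, 1.85, 1.98,
         2.27, 1.73, 1.39, 2.31, 2.00, 1.90)
  names(r) <- c("H", "C", "N", "O", "S", "P", "F", "CL", "BR", "I",
                "NA", "MG", "ZN", "CA", "FE", "SE")
  r
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Each atom is inflated by the probe radius and covered with a
#' deterministic Fibonacci point set; a point is exposed iff it lies
#' outside every other inflated sphere.  Area is the exposed fraction
#' times the inflated-sphere area.  Zero-radius atoms contribute their
#' probe-sphere area.
#'
#' @param solute A [solute_system()].
#' @param probe Probe radius, A (default 1.4, a water molecule).
#' @param n_points Quadrature points per atom (default 960).
#' @param radii Optional numeric vector overriding the per-atom vdW
#'   radii (defaults to the solute's `radius` column; atoms with radius
#'   0 keep 0).
#' @return List of class `sasa_result`: `total` (A^2), `per_atom`,
#'   `per_residue` (named by `resno`), `probe`, `n_points`.
#' @export
sasa <- function(solute, probe = 1.4, n_points = 960L, radii = NULL) {
  a <- solute$atoms
  if (is.null(radii)) radii <- a$radius
  if (length(radii) != nrow(a)) stop("radii length mismatch")
  pts <- fibonacci_sphere(n_points)
  pos <- cbind(a$x, a$y, a$z)
  rr <- radii + probe
  n <- nrow(a)
  per_atom <- numeric(n)
  for (i in seq_len(n)) {
    # neighbors whose inflated spheres can reach atom i's shell
    d2 <- colSums((t(pos) - pos[i, ])^2)
    nb <- which(d2 < (rr + rr[i])^2 & seq_len(n) != i)
    p <- sweep(pts * rr[i], 2, pos[i, ], "+")
    exposed <- rep(TRUE, n_points)
    for (j in nb) {
      if (!any(exposed)) break
      d2p <- (p[exposed, 1] - pos[j, 1])^2 + (p[exposed, 2] - pos[j, 2])^2 +
        (p[exposed, 3] - pos[j, 3])^2
      exposed[exposed] <- d2p >= rr[j]^2
    }
    per_atom[i] <- sum(exposed) / n_points * 4 * pi * rr[i]^2
  }
  per_res <- tapply(per_atom, a$resno, sum)
  structure(list(total = sum(per_atom), per_atom = per_atom,
                 per_residue = per_res, probe = probe,
                 n_points = n_points),
            class = "sasa_result")
}

#' @export
print.sasa_result <- function(x, ...) {
  cat(sprintf("<sasa_result>  total %.2f A^2 (probe %.2f A, %d points/atom)\n",
              x$total, x$probe, x$n_points))
  invisible(x)
}
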