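# 1D site-site RISM (XRISM) for the bulk solvent: produces the solvent
# susceptibility chi_ab(k) consumed by the 3D stage.
#
# Renormalized (Ng) scheme: the site-site potential is split as
#   u = u_short + u_long,  u_long = C q_a q_b erf(eta r) / r,
# the long-range part of the direct correlation is carried analytically
# in k-space (a Gaussian-screened Coulomb), and the iteration variable
# is the short-range direct correlation c_short per distinct site pair.

#' Lennard-Jones 12-6 potential
#'
#' @param r Distances, Angstrom (> 0).
#' @param sigma LJ diameter, Angstrom; `sigma = 0` means no LJ term.
#' @param epsilon Well depth, kcal/mol.
#' @return Energies, kcal/mol.
#' @export
lj_potential <- function(r, sigma, epsilon) {
  if (sigma <= 0 || epsilon <= 0) return(rep(0, length(r)))
  sr6 <- (sigma / r)^6
  4 * epsilon * (sr6 * sr6 - sr6)
}

#' @keywords internal
sinc <- function(x) ifelse(x == 0, 1, sin(x) / x)

#' Intramolecular correlation matrix of a rigid solvent
#'
#' For a rigid molecule, `omega_ag(k) = sin(k l_ag) / (k l_ag)` for
#' distinct sites at fixed separation `l_ag`, and 1 on the diagonal
#' (the k -> 0 limit of the sinc is handled analytically).
#'
#' @param model A [solvent_model()].
#' @param grid A [radial_grid()].
#' @return Array `[n_k, n_sites, n_sites]` with site labels in dimnames.
#' @export
build_intramolecular <- function(model, grid) {
  pos <- t(vapply(model$sites, `[[`, numeric(3), "position"))
  n <- nrow(pos)
  labels <- vapply(model$sites, `[[`, "", "name")
  k <- grid$k
  w <- array(0, dim = c(length(k), n, n),
             dimnames = list(NULL, labels, labels))
  for (a in seq_len(n)) for (b in seq_len(n)) {
    if (a == b) { w[, a, b] <- 1; next }
    l <- sqrt(sum((pos[a, ] - pos[b, ])^2))
    if (l <= 1e-8)
      stop("invalid model: zero intramolecular distance between distinct sites")
    w[, a, b] <- sinc(k * l)
  }
  w
}

# ---- batched small-matrix algebra over the k grid ------------------------
# Arrays are [n_k, n, n]; operations vectorize over the first index.

#' @keywords internal
batch_matmul <- function(A, B) {
  n <- dim(A)[2]
  C <- array(0, dim = dim(A))
  for (a in seq_len(n)) for (b in seq_len(n)) {
    acc <- A[, a, 1] * B[, 1, b]
    if (n > 1L) for (m in 2:n) acc <- acc + A[, a, m] * B[, m, b]
    C[, a, b] <- acc
  }
  C
}

#' @keywords internal
batch_inv <- function(A) {
  n <- dim(A)[2]
  out <- array(0, dim = dim(A))
  if (n == 1L) {
    out[, 1, 1] <- 1 / A[, 1, 1]
  } else if (n == 2L) {
    det <- A[, 1, 1] * A[, 2, 2] - A[, 1, 2] * A[, 2, 1]
    out[, 1, 1] <- A[, 2, 2] / det; out[, 2, 2] <- A[, 1, 1] / det
    out[, 1, 2] <- -A[, 1, 2] / det; out[, 2, 1] <- -A[, 2, 1] / det
  } else if (n == 3L) {
    a <- A[, 1, 1]; b <- A[, 1, 2]; c <- A[, 1, 3]
    d <- A[, 2, 1]; e <- A[, 2, 2]; f <- A[, 2, 3]
    g <- A[, 3, 1]; h <- A[, 3, 2]; i <- A[, 3, 3]
    C11 <- e * i - f * h; C12 <- -(d * i - f * g); C13 <- d * h - e * g
    C21 <- -(b * i - c * h); C22 <- a * i - c * g; C23 <- -(a * h - b * g)
    C31 <- b * f - c * e; C32 <- -(a * f - c * d); C33 <- a * e - b * d
    det <- a * C11 + b * C12 + c * C13
    out[, 1, 1] <- C11 / det; out[, 1, 2] <- C21 / det; out[, 1, 3] <- C31 / det
    out[, 2, 1] <- C12 / det; out[, 2, 2] <- C22 / det; out[, 2, 3] <- C32 / det
    out[, 3, 1] <- C13 / det; out[, 3, 2] <- C23 / det; out[, 3, 3] <- C33 / det
  } else {
    for (j in seq_len(dim(A)[1])) out[j, , ] <- solve(A[j, , ])
  }
  out
}

# ---- 1D RISM solve -------------------------------------------------------

#' Solve the 1D site-site RISM equations for a bulk solvent
#'
#' Iterates the matrix OZ equation `h = w c w + w c rho h` (distinct-site
#' form, molecular density on the diagonal of rho) together with the KH
#' or HNC closure to convergence, then assembles the solvent
#' susceptibility `chi_ab(k) = omega_ab(k) + rho h_ab(k)` per distinct
#' site-type pair.
#'
#' @param model A [solvent_model()].
#' @param grid A [radial_grid()]; the default (2^13 points, dr = 0.01 A)
#'   resolves the O-H contact peak and covers the k range any practical
#'   3D box needs.
#' @param closure `"kh"` or `"hnc"`.
#' @param options List overriding iteration controls: `tol` (max-norm
#'   residual on c_short, default 1e-8), `max_iter` (default 20000),
#'   `n_vectors` (MDIIS subspace, default 5; 1 = damped Picard), `damp`
#'   (default 0.5), `eta` (Coulomb splitting parameter, 1/A, default 1.0).
#' @return An object of class `susceptibility_table`: `k`, `chi` and
#'   `omega` (matrices `[n_k, n_pairs]`, pair columns named
#'   `"A:B"`), `pair_types`, `site_table` (with per-site densities),
#'   `r`, `g` (site-site radial distribution functions at convergence),
#'   `closure`, `residual`, `iterations`, plus model/state-point
#'   provenance.
#' @export
solve_rism1d <- function(model, grid = radial_grid(),
                         closure = c("kh", "hnc"), options = list()) {
  closure <- match.arg(closure)
  opt <- utils::modifyList(
    list(tol = 1e-8, max_iter = 20000L, n_vectors = 5L, damp = 0.5,
         eta = 1.0), options)
  st <- solvent_site_table(model)
  nt <- nrow(st)
  labels <- vapply(model$sites, `[[`, "", "name")
  type_of <- match(labels, st$type)
  n <- length(labels)
  rho <- model$density
  beta <- 1 / kT_kcal(model$temperature)
  r <- grid$r; k <- grid$k; nk <- grid$n_points

  pairs <- which(upper.tri(matrix(0, nt, nt), diag = TRUE), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  np <- nrow(pairs)
  pair_names <- paste(st$type[pairs[, 1]], st$type[pairs[, 2]], sep = ":")
  # map (type_a, type_b) -> pair column
  pair_index <- matrix(0L, nt, nt)
  for (p in seq_len(np)) {
    pair_index[pairs[p, 1], pairs[p, 2]] <- p
    pair_index[pairs[p, 2], pairs[p, 1]] <- p
  }

  eta <- opt$eta
  bu_s <- matrix(0, nk, np)   # short-range potential, kT units
  cl_k <- matrix(0, nk, np)   # analytic long-range c in k-space
  for (p in seq_len(np)) {
    i <- pairs[p, 1]; j <- pairs[p, 2]
    sig <- (st$sigma[i] + st$sigma[j]) / 2
    eps <- sqrt(st$epsilon[i] * st$epsilon[j])
    qq <- st$charge[i] * st$charge[j]
    u <- lj_potential(r, sig, eps) +
      COULOMB_KCAL * qq * erfc_(eta * r) / r
    bu_s[, p] <- beta * u
    cl_k[, p] <- -beta * COULOMB_KCAL * qq * 4 * pi *
      exp(-k^2 / (4 * eta^2)) / k^2
  }

  omega_atom <- build_intramolecular(model, grid)

  # type-collapsed symmetric intramolecular function:
  # omega_ab(k) = (1/m_a) sum_{a' in a} omega_{a' b0}(k)
  rep_atom <- match(st$type, labels)
  omega_pair <- matrix(0, nk, np)
  for (p in seq_len(np)) {
    a <- pairs[p, 1]; b <- pairs[p, 2]
    members <- which(type_of == a)
    acc <- 0
    for (m in members) acc <- acc + omega_atom[, m, rep_atom[b]]
    omega_pair[, p] <- acc / length(members)
  }

  ident <- array(0, dim = c(nk, n, n))
  for (a in seq_len(n)) ident[, a, a] <- 1

  last <- new.env(parent = emptyenv())
  residual_fun <- function(cs_vec) {
    cs <- matrix(cs_vec, nk, np)
    cs_k <- matrix(0, nk, np)
    for (p in seq_len(np)) cs_k[, p] <- radial_fft(cs[, p], grid)
    c_k <- cs_k + cl_k
    Ck <- array(0, dim = c(nk, n, n))
    for (a in seq_len(n)) for (b in seq_len(n))
      Ck[, a, b] <- c_k[, pair_index[type_of[a], type_of[b]]]
    WC <- batch_matmul(omega_atom, Ck)
    M <- ident - rho * WC
    H <- batch_matmul(batch_inv(M), batch_matmul(WC, omega_atom))
    h_k <- matrix(0, nk, np)
    for (p in seq_len(np)) {
      a <- pairs[p, 1]; b <- pairs[p, 2]
      sel_a <- which(type_of == a); sel_b <- which(type_of == b)
      acc <- 0
      for (ia in sel_a) for (ib in sel_b) acc <- acc + H[, ia, ib]
      h_k[, p] <- acc / (length(sel_a) * length(sel_b))
    }
    tstar_k <- h_k - cs_k
    tstar <- matrix(0, nk, np)
    for (p in seq_len(np)) tstar[, p] <- radial_ifft(tstar_k[, p], grid)
    upd <- kh_closure(bu_s, tstar, closure)
    last$g <- upd$g; last$tstar <- tstar; last$h_k <- h_k
    as.numeric(upd$c_short) - cs_vec
  }

  cs0 <- exp(-pmin(bu_s, 500)) - 1   # Mayer-function start
  sol <- mdiis_solve(as.numeric(cs0), residual_fun,
                     n_vectors = opt$n_vectors, tol = opt$tol,
                     max_iter = opt$max_iter, damp = opt$damp)
  invisible(residual_fun(sol$x))  # refresh `last` at the solution

  chi <- omega_pair + rho * last$h_k
  colnames(chi) <- colnames(omega_pair) <- pair_names
  g <- last$g
  colnames(g) <- pair_names

  structure(
    list(k = k, dk = grid$dk, r = r, dr = grid$dr,
         n_points = grid$n_points,
         chi = chi, omega = omega_pair,
         pair_types = cbind(st$type[pairs[, 1]], st$type[pairs[, 2]]),
         site_table = st,
         g = g,
         model_name = model$name, density = rho,
         temperature = model$temperature, closure = closure,
         eta = eta,
         residual = sol$residual, iterations = sol$iterations,
         converged = sol$converged),
    class = "susceptibility_table")
}

#' @export
print.susceptibility_table <- function(x, ...) {
  cat(sprintf(
    "<susceptibility_table '%s'>  %s closure, %d k-points (dk = %.4g 1/A)\n",
    x$model_name, toupper(x$closure), x$n_points, x$dk))
  cat(sprintf("  pairs: %s\n", paste(colnames(x$chi), collapse = ", ")))
  cat(sprintf("  residual %.3e after %d iterations\n", x$residual, x$iterations))
  invisible(x)
}

#' Look up chi for one site-type pair
#'
#' @param table A `susceptibility_table`.
#' @param a,b Site-type labels.
#' @return chi_ab on the table's k grid.
#' @export
chi_pair <- function(table, a, b) {
  nm <- paste(a, b, sep = ":")
  nm2 <- paste(b, a, sep = ":")
  cn <- colnames(table$chi)
  j <- match(nm, cn)
  if (is.na(j)) j <- match(nm2, cn)
  if (is.na(j)) stop(sprintf("no pair %s in susceptibility table", nm))
  table$chi[, j]
}

# erfc without extra dependencies (complement via pnorm)
#' @keywords internal
erfc_ <- function(x) 2 * stats::pnorm(-x * sqrt(2))

#' @keywords internal
erf_ <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1

#' Write / read a susceptibility table as a plain-text file
#'
#' A versioned, self-describing text format: `#`-prefixed header lines
#' (`key: value`) recording model, state point, closure, grid and
#' convergence, then whitespace-separated columns `k`, `chi_<pair>...`,
#' `omega_<pair>...`.
#'
#' @param table A `susceptibility_table`.
#' @param path Output file.
#' @return `write_susceptibility`: the path, invisibly.
#'   `read_susceptibility`: a `susceptibility_table` (without the
#'   real-space diagnostics fields).
#' @export
write_susceptibility <- function(table, path) {
  st <- table$site_table
  hdr <- c(
    "# rismhydra susceptibility table v1",
    sprintf("# model: %s", table$model_name),
    sprintf("# temperature: %.6g", table$temperature),
    sprintf("# density: %.8g", table$density),
    sprintf("# closure: %s", table$closure),
    sprintf("# eta: %.6g", table$eta),
    sprintf("# n_points: %d", table$n_points),
    sprintf("# dr: %.10g", table$dr),
    sprintf("# residual: %.6e", table$residual),
    sprintf("# site: %s %d %.6g %.6g %.6g %.8g",
            st$type, st$multiplicity, st$charge, st$sigma, st$epsilon,
            st$rho_site),
    sprintf("# pairs: %s", paste(colnames(table$chi), collapse = " ")))
  dat <- cbind(table$k, table$chi, table$omega)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(format(dat, digits = 12, scientific = TRUE),
                     con, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_susceptibility
#' @export
read_susceptibility <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  getv <- function(key) {
    ln <- hdr[grepl(paste0("^# ", key, ":"), hdr)]
    sub(paste0("^# ", key, ": *"), "", ln[1])
  }
  site_lines <- hdr[startsWith(hdr, "# site:")]
  st <- do.call(rbind, lapply(site_lines, function(ln) {
    f <- strsplit(sub("^# site: *", "", ln), " +")[[1]]
    data.frame(type = f[1], multiplicity = as.integer(f[2]),
               charge = as.numeric(f[3]), sigma = as.numeric(f[4]),
               epsilon = as.numeric(f[5]), rho_site = as.numeric(f[6]),
               stringsAsFactors = FALSE)
  }))
  pair_names <- strsplit(getv("pairs"), " +")[[1]]
  np <- length(pair_names)
  dat <- utils::read.table(text = lines[!startsWith(lines, "#")])
  chi <- as.matrix(dat[, 2:(1 + np)])
  omega <- as.matrix(dat[, (2 + np):(1 + 2 * np)])
  colnames(chi) <- colnames(omega) <- pair_names
  pt <- do.call(rbind, strsplit(pair_names, ":", fixed = TRUE))
  dr <- as.numeric(getv("dr")); npts <- as.integer(getv("n_points"))
  structure(
    list(k = dat[, 1], dk = dat[2, 1] - dat[1, 1],
         r = seq_len(npts) * dr, dr = dr, n_points = npts,
         chi = chi, omega = omega, pair_types = pt, site_table = st,
         g = NULL, model_name = getv("model"),
         density = as.numeric(getv("density")),
         temperature = as.numeric(getv("temperature")),
         closure = getv("closure"), eta = as.numeric(getv("eta")),
         residual = as.numeric(getv("residual")),
         iterations = NA_integer_, converged = TRUE),
    class = "susceptibility_table")
}
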