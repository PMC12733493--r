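# 1D solvent stage: intramolecular correlations, limits, water physics

test_that("intramolecular correlation has sinc structure with exact limits", {
  m <- solvent_catalogue("mspce")
  grid <- radial_grid(512L, 0.05)
  w <- build_intramolecular(m, grid)
  expect_equal(dim(w), c(512L, 3L, 3L))
  # diagonal identity for every site and k
  for (i in 1:3) expect_true(all(w[, i, i] == 1))
  # sinc zero: l = 1.0 A (O-H bond), k = pi 1/A
  l_oh <- 1.0
  j <- which.min(abs(grid$k - pi))
  expect_equal(w[j, 1, 2], sin(grid$k[j] * l_oh) / (grid$k[j] * l_oh),
               tolerance = 1e-5)
  expect_lt(abs(sin(pi * l_oh) / (pi * l_oh)), 1e-12)
  # k -> 0 limit approaches 1 (sinc ~ 1 - (k l)^2/6 at the smallest k)
  k1 <- grid$k[1]
  expect_equal(w[1, 1, 2], 1 - (k1 * l_oh)^2 / 6, tolerance = 1e-4)
  # symmetry of the atom-level matrix
  expect_equal(w[, 1, 2], w[, 2, 1])
})

test_that("coincident distinct sites are rejected", {
  expect_error(
    solvent_model(list(
      solvent_site("A", 0.5, 1, 0.1, c(0, 0, 0)),
      solvent_site("B", -0.5, 1, 0.1, c(0, 0, 0))),
      density = 0.01, temperature = 300),
    "zero separation")
})

test_that("zero interactions give the ideal-gas susceptibility chi = omega", {
  grid <- radial_grid(2048L, 0.02)
  s <- solve_rism1d(noninteracting_water(), grid)
  expect_true(s$converged)
  expect_lt(max(abs(s$chi - s$omega)), 1e-8)
  expect_lt(max(abs(s$g - 1)), 1e-8)
})

test_that("low-density LJ fluid recovers the Mayer-function limit", {
  grid <- radial_grid(2048L, 0.02)
  m <- solvent_model(list(solvent_site("X", 0, 3.166, 0.1553, c(0, 0, 0))),
                     density = 1e-6, temperature = 298.15)
  s <- solve_rism1d(m, grid, closure = "hnc")
  beta <- 1 / (0.0019872041 * 298.15)
  mayer <- exp(-pmin(beta * lj_potential(grid$r, 3.166, 0.1553), 500)) - 1
  # at rho -> 0, h -> Mayer function (and c -> h)
  expect_lt(max(abs((s$g[, 1] - 1) - mayer)), 1e-4)
})

test_that("MSPC/E water at ambient conditions has a physical O-O structure", {
  s <- water_chi()
  expect_true(s$converged)
  expect_lt(s$residual, 1e-8)
  g <- s$g[, "Ow:Ow"]
  r <- s$r
  ipk <- which.max(g[r < 4])
  expect_gt(r[ipk], 2.6)
  expect_lt(r[ipk], 3.0)
  expect_true(all(s$g >= 0))
  # susceptibility is symmetric by construction: both lookup orders agree
  expect_identical(chi_pair(s, "Ow", "Hw"), chi_pair(s, "Hw", "Ow"))
  # finite everywhere
  expect_true(all(is.finite(s$chi)))
})

test_that("halving dr moves the O-O first peak by less than one coarse bin", {
  s_coarse <- water_chi_fast()    # dr = 0.02
  s_fine <- water_chi()           # dr = 0.01
  peak_of <- function(s) {
    g <- s$g[, "Ow:Ow"]; r <- s$r
    r[which.max(g[r < 4])]
  }
  expect_lt(abs(peak_of(s_fine) - peak_of(s_coarse)), 0.02 + 1e-12)
})

test_that("susceptibility tables round-trip through the text format", {
  s <- water_chi_fast()
  tf <- withr::local_tempfile(fileext = ".dat")
  write_susceptibility(s, tf)
  s2 <- read_susceptibility(tf)
  expect_equal(s2$chi, s$chi, tolerance = 1e-10)
  expect_equal(s2$omega, s$omega, tolerance = 1e-10)
  expect_equal(s2$k, s$k, tolerance = 1e-10)
  expect_equal(s2$density, s$density)
  expect_equal(s2$site_table$rho_site, s$site_table$rho_site)
  expect_equal(s2$closure, s$closure)
})

test_that("non-convergence raises a divergence error carrying the residual", {
  m <- solvent_catalogue("mspce")
  err <- tryCatch(
    solve_rism1d(m, radial_grid(1024L, 0.04),
                 options = list(max_iter = 3L, tol = 1e-14)),
    rismhydra_divergence = function(e) e)
  expect_s3_class(err, "rismhydra_divergence")
  expect_true(is.finite(err$residual))
  expect_true(length(err$trace) >= 1)
})
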