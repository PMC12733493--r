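# 3D grid construction and the solute-site potential

test_that("grid shapes are even and 7-smooth over random extents", {
  set.seed(11)
  for (rep in 1:25) {
    n <- fft_friendly_size(runif(1, 3, 700))
    expect_equal(n %% 2L, 0L)
    m <- n
    for (p in c(2L, 3L, 5L, 7L)) while (m %% p == 0L) m <- m %/% p
    expect_equal(m, 1L)
  }
})

test_that("a buffered box fully contains the solute plus buffer", {
  s <- make_toy_solute(fixture_recipe("lj_sphere"))
  g <- build_grid(s, buffer = 10, spacing = 0.25)
  expect_true(all(g$shape >= 80L))
  ext <- g$origin + (g$shape - 1) * g$spacing
  expect_true(all(g$origin <= -10))
  expect_true(all(ext >= 10))
})

test_that("the memory ceiling raises a deterministic size error", {
  s <- make_toy_solute(fixture_recipe("lj_sphere"))
  expect_error(build_grid(s, buffer = 12, spacing = 0.1, max_bytes = 1e6),
               "memory ceiling")
  expect_error(build_grid(s, buffer = 12, spacing = 0.1, max_bytes = 1e6),
               "bytes")
})

test_that("a non-interacting solute produces an identically zero potential", {
  a <- data.frame(serial = 1L, name = "X", element = "C", resid = "TOY",
                  resno = 1L, chain = "A", x = 0, y = 0, z = 0,
                  charge = 0, sigma = 0, epsilon = 0, radius = 1)
  s <- solute_system(a)
  grid <- grid_spec(rep(-4, 3), 0.5, 16L)
  site <- list(charge = -0.8476, sigma = 3.166, epsilon = 0.1553)
  p <- build_potential(s, site, grid)
  expect_true(all(p$u_short == 0))
  expect_true(all(p$u_long_k == 0))
})

test_that("LJ term vanishes at the combined sigma and cores are capped", {
  a <- data.frame(serial = 1L, name = "X", element = "C", resid = "TOY",
                  resno = 1L, chain = "A", x = 0, y = 0, z = 0,
                  charge = 0, sigma = 3.0, epsilon = 0.2, radius = 1)
  s <- solute_system(a)
  site <- list(charge = 0, sigma = 3.3, epsilon = 0.1)
  sig_c <- (3.0 + 3.3) / 2
  # grid chosen so a node lands exactly at r = sigma_comb on the x axis
  grid <- grid_spec(c(-sig_c * 2, -sig_c * 2, -sig_c * 2), sig_c / 2, 9L)
  p <- build_potential(s, site, grid)
  expect_equal(p$u_short[7, 5, 5], 0, tolerance = 1e-12)   # node at exactly sigma_comb
  # atom center is capped, never NaN/Inf
  expect_equal(p$u_short[5, 5, 5], p$core_cap)
  expect_true(all(is.finite(p$u_short)))
})

test_that("short-range + analytic erf complement equals the bare Coulomb sum", {
  set.seed(3)
  a <- data.frame(serial = 1L, name = "X", element = "C", resid = "TOY",
                  resno = 1L, chain = "A", x = 0, y = 0, z = 0,
                  charge = 1, sigma = 0, epsilon = 0, radius = 1)
  s <- solute_system(a)
  site <- list(charge = -0.8476, sigma = 0, epsilon = 0)
  grid <- grid_spec(rep(-16, 3), 0.5, 64L)
  eta <- 0.5
  p <- build_potential(s, site, grid, eta = eta)
  beta <- 1 / (0.0019872041 * 298.15)
  # 64 random far-field grid nodes at r in [8, 12]
  ax <- lapply(1:3, function(i) grid$origin[i] + (0:63) * 0.5)
  idx <- matrix(sample(10:54, 3 * 200, replace = TRUE), ncol = 3)
  r <- sqrt(ax[[1]][idx[, 1]]^2 + ax[[2]][idx[, 2]]^2 + ax[[3]][idx[, 3]]^2)
  keep <- which(r > 8 & r < 12)[1:64]
  idx <- idx[keep, ]; r <- r[keep]
  u_direct <- beta * (-0.8476) * 332.06371 / r
  u_split <- p$u_short[idx] +
    beta * (-0.8476) * 332.06371 * (2 * pnorm(eta * r * sqrt(2)) - 1) / r
  expect_equal(u_split, u_direct, tolerance = 1e-10)
})

test_that("k-space long-range part reconstructs the erf potential of a neutral pair", {
  a <- data.frame(serial = 1:2, name = c("P", "M"), element = "C",
                  resid = "TOY", resno = 1L, chain = "A",
                  x = c(1.0, -1.0), y = 0, z = 0,
                  charge = c(1, -1), sigma = 0, epsilon = 0, radius = 1)
  s <- solute_system(a)
  site <- list(charge = 0.4238, sigma = 0, epsilon = 0)
  grid <- grid_spec(rep(-20, 3), 0.625, 64L)
  eta <- 0.5
  p <- build_potential(s, site, grid, eta = eta)
  ul <- u_long_real(p)
  beta <- 1 / (0.0019872041 * 298.15)
  ax <- lapply(1:3, function(i) grid$origin[i] + (0:63) * 0.625)
  # direct sum of the erf-damped tails; near the dipole agreement is
  # relative, far out the (small) periodic images bound the error
  erf_ <- function(x) 2 * pnorm(x * sqrt(2)) - 1
  u_direct <- function(pt) {
    x <- c(ax[[1]][pt[1]], ax[[2]][pt[2]], ax[[3]][pt[3]])
    u_ref <- 0
    for (i in 1:2) {
      ri <- sqrt(sum((x - c(a$x[i], a$y[i], a$z[i]))^2))
      u_ref <- u_ref + beta * 0.4238 * a$charge[i] * 332.06371 *
        erf_(eta * ri) / ri
    }
    u_ref
  }
  for (pt in list(c(30, 33, 33), c(36, 33, 33), c(33, 36, 36))) {
    u_ref <- u_direct(pt)
    expect_equal(ul[pt[1], pt[2], pt[3]], u_ref,
                 tolerance = 0.01 + 0.35 / abs(u_ref))
  }
  for (pt in list(c(20, 33, 33), c(40, 33, 33)))
    expect_lt(abs(ul[pt[1], pt[2], pt[3]] - u_direct(pt)), 0.35)
})
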