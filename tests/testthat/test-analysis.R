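# Hydration analysis: distance transform, shell profile, boundary
# criterion, hydration numbers, pockets, H-bond classification

test_that("distance transform is exact against the brute-force oracle", {
  s <- make_toy_solute(fixture_recipe("polyatomic_random", n = 10L,
                                      seed = 3L))
  grid <- grid_spec(rep(-8, 3), 0.8, 20L)
  df <- distance_transform(s, grid)
  # independent all-pairs oracle
  ax <- lapply(1:3, function(i) grid$origin[i] + (0:19) * 0.8)
  pts <- as.matrix(expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]]))
  a <- s$atoms
  dmin <- rep(Inf, nrow(pts)); imin <- rep(NA_integer_, nrow(pts))
  for (i in seq_len(nrow(a))) {
    di <- sqrt((pts[, 1] - a$x[i])^2 + (pts[, 2] - a$y[i])^2 +
                 (pts[, 3] - a$z[i])^2)
    upd <- di < dmin
    dmin[upd] <- di[upd]; imin[upd] <- i
  }
  expect_equal(as.numeric(df$d), dmin, tolerance = 1e-12)
  expect_equal(as.integer(df$nearest), imin)
})

test_that("distance field obeys forced single- and two-atom geometry", {
  a <- data.frame(serial = 1L, name = "X", element = "C", resid = "TOY",
                  resno = 1L, chain = "A", x = 0, y = 0, z = 0,
                  charge = 0, sigma = 3, epsilon = 0.1, radius = 1.5)
  s1 <- solute_system(a)
  grid <- grid_spec(rep(-2, 3), 0.5, 9L)   # node 5 is exactly the origin
  d1 <- distance_transform(s1, grid)
  expect_equal(d1$d[5, 5, 5], 0)
  expect_equal(d1$d[6, 5, 5], 0.5)
  expect_equal(d1$d[5, 4, 5], 0.5)
  # surface mode subtracts the radius, clamped at zero
  ds <- distance_transform(s1, grid, mode = "surface")
  expect_equal(ds$d[5, 5, 5], 0)
  expect_equal(max(abs(ds$d - pmax(d1$d - 1.5, 0))), 0)
  # two atoms: pointwise minimum of the single-atom fields
  a2 <- rbind(a, within(a, { x <- 1.5; serial <- 2L }))
  s2 <- solute_system(a2)
  d2 <- distance_transform(s2, grid)
  s1b <- solute_system(within(a, { x <- 1.5 }))
  d1b <- distance_transform(s1b, grid)
  expect_equal(d2$d, pmin(d1$d, d1b$d), tolerance = 1e-12)
  # 1-Lipschitz along grid axes
  dd <- d2$d
  expect_lte(max(abs(dd[-1, , ] - dd[-9, , ])), 0.5 + 1e-12)
})

test_that("bulk and vacuum fields give exact trivial shell profiles", {
  s <- make_toy_solute(fixture_recipe("lj_sphere"))
  grid <- grid_spec(rep(-8, 3), 0.5, 32L)
  df <- distance_transform(s, grid)
  rho <- 0.03332
  g1 <- array(1, dim = grid$shape)
  p1 <- shell_profile(g1, df, rho, bin = 0.5)
  ok <- !is.na(p1$shell_density)
  expect_equal(p1$shell_density[ok], rep(1, sum(ok)), tolerance = 1e-12)
  # n equals rho * voxelized shell volume exactly for g = 1
  j <- 10
  expect_equal(p1$n[j + 1], rho * sum(df$d <= p1$r[j + 1]) * grid$dv,
               tolerance = 1e-12)
  g0 <- array(0, dim = grid$shape)
  p0 <- shell_profile(g0, df, rho, bin = 0.5)
  expect_true(all(p0$n == 0))
  expect_true(all(p0$n_prime[!is.na(p0$n_prime)] == 0))
  # a bin finer than the grid spacing is refused
  expect_error(shell_profile(g1, df, rho, bin = 0.2), "alias")
})

test_that("painted radial shells integrate like the 1D quadrature oracle", {
  s <- make_toy_solute(fixture_recipe("lj_sphere"))
  grid <- grid_spec(rep(-8, 3), 0.25, 64L)
  df <- distance_transform(s, grid)
  g <- paint_radial_field(shell_gfun, s, grid, dist = df)
  rho <- 0.03332
  r_cut <- 4.0
  n_grid <- hydration_number(g, df, r_cut, rho)
  rr <- seq(0, r_cut, length.out = 4001)
  n_quad <- rho * 4 * pi * sum(rr^2 * shell_gfun(rr)) * (rr[2] - rr[1])
  expect_equal(n_grid, n_quad, tolerance = 0.01)
  # profile recovers the constructed boundary near 4 A
  pr <- shell_profile(g, df, rho, bin = 0.25)
  b <- find_shell_boundary(pr)
  expect_equal(b$r_cut, 4.0, tolerance = 0.25)
  expect_false(b$weak)
})

test_that("boundary detection handles flat and synthetic profiles", {
  flat <- as_shell_profile(seq(0.1, 8, by = 0.1), rep(1, 80))
  expect_error(find_shell_boundary(flat),
               class = "rismhydra_no_boundary")
  # monotone profile: no peak above bulk
  mono <- as_shell_profile(seq(0.1, 8, by = 0.1),
                           seq(0.2, 1, length.out = 80))
  expect_error(find_shell_boundary(mono),
               class = "rismhydra_no_boundary")
  sp <- make_shell_profile(seed = 42L)
  b <- find_shell_boundary(sp$profile)
  expect_equal(b$r_cut, sp$true_trough, tolerance = sp$profile$bin)
})

test_that("hydration number is monotone in r_cut and range-checked", {
  s <- make_toy_solute(fixture_recipe("lj_sphere"))
  grid <- grid_spec(rep(-8, 3), 0.5, 32L)
  df <- distance_transform(s, grid)
  g <- paint_radial_field(shell_gfun, s, grid, dist = df)
  ns <- vapply(seq(1, 7, by = 0.5), function(rc)
    hydration_number(g, df, rc, 0.03332), 0)
  expect_true(all(diff(ns) >= 0))
  expect_error(hydration_number(g, df, 100, 0.03332), "range")
})

test_that("pocket counts partition the total hydration number exactly", {
  s <- make_toy_solute(fixture_recipe("polyatomic_random", n = 8L,
                                      seed = 9L))
  grid <- grid_spec(rep(-10, 3), 0.5, 40L)
  df <- distance_transform(s, grid)
  g <- paint_radial_field(function(d) 1 + exp(-(d - 3)^2), s, grid,
                          dist = df)
  rho <- 0.03332
  r_cut <- 5
  n_tot <- hydration_number(g, df, r_cut, rho)
  all_res <- pocket_spec("all", unique(s$atoms$resno))
  expect_equal(pocket_hydration(g, df, s, all_res, r_cut, rho), n_tot,
               tolerance = 1e-12)
  p1 <- pocket_spec("half1", 1:4)
  p2 <- pocket_spec("half2", 5:8)
  c1 <- pocket_hydration(g, df, s, p1, r_cut, rho)
  c2 <- pocket_hydration(g, df, s, p2, r_cut, rho)
  expect_equal(c1 + c2, n_tot, tolerance = 1e-12)
  expect_error(pocket_hydration(g, df, s, pocket_spec("bad", 99L),
                                r_cut, rho),
               "absent")
  expect_error(pocket_hydration(g, df, s,
                                pocket_spec("bad", 1L, resid = "XYZ"),
                                r_cut, rho),
               "expected XYZ")
})

test_that("the shipped Sudlow pocket lists load with the printed sizes", {
  pk <- sudlow_sites()
  expect_named(pk, c("sudlow_I", "sudlow_II"))
  expect_length(pk$sudlow_I$resno, 33L)
  expect_length(pk$sudlow_II$resno, 18L)
  expect_true(150 %in% pk$sudlow_I$resno)
  expect_true(411 %in% pk$sudlow_II$resno)
})

test_that("polar-atom classification and apolar / vacuum H-bond limits", {
  w <- make_toy_solute(fixture_recipe("rigid_water_solute"))
  pol <- classify_polar_atoms(w)
  expect_equal(pol$acceptors, 1L)          # the oxygen
  expect_equal(pol$donors, 1L)             # same oxygen carries both H
  apolar <- make_toy_solute(fixture_recipe("lj_sphere"))
  grid <- grid_spec(rep(-8, 3), 0.5, 32L)
  df <- distance_transform(apolar, grid)
  g1 <- array(1, dim = grid$shape)
  expect_message(
    fr <- hbond_fraction(g1, g1, apolar, df, 4, 0.03332),
    "no polar atoms")
  expect_equal(as.numeric(fr), 0)
  # vacuum fields around a polar solute
  dfw <- distance_transform(w, grid)
  g0 <- array(0, dim = grid$shape)
  fr0 <- hbond_fraction(g0, g0, w, dfw, 4, 0.03332)
  expect_equal(as.numeric(fr0), 0)
  # saturated fields clamp with a warning
  gbig <- array(50, dim = grid$shape)
  expect_warning(
    frc <- hbond_fraction(gbig, g1, w, dfw, 4, 0.03332), "clamped")
  expect_equal(as.numeric(frc), 1)
})
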