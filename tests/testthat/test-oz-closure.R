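# Closure relation and Ornstein-Zernike convolution

test_that("KH closure branches meet at d = 0 with matching value and slope", {
  eps <- 1e-8
  expect_equal(closure_g(0, "kh"), 1)
  expect_equal(closure_g(0, "hnc"), 1)
  # value continuity
  expect_equal(closure_g(-eps, "kh"), closure_g(eps, "kh"),
               tolerance = 1e-7)
  # slope continuity: both one-sided derivatives equal 1
  sl_lo <- (closure_g(0, "kh") - closure_g(-eps, "kh")) / eps
  sl_hi <- (closure_g(eps, "kh") - closure_g(0, "kh")) / eps
  expect_equal(sl_lo, 1, tolerance = 1e-6)
  expect_equal(sl_hi, 1, tolerance = 1e-6)
})

test_that("KH closure evaluates exactly on scalar cases", {
  # zero fields: g = 1, both branches agree
  up <- kh_closure(0, 0)
  expect_equal(up$g, 1)
  expect_equal(up$c_short, 0)
  # capped hard core: g = exp(-40)
  expect_equal(kh_closure(40, 0)$g, exp(-40))
  # depleted region: u/kT = 1, h = 0.2, c = 0.1 -> d = -0.9
  d <- -1 + (0.2 - 0.1)
  expect_equal(kh_closure(1, 0.2 - 0.1)$g, exp(d))
  # exponential branch everywhere below zero
  dd <- seq(-5, 0, by = 0.25)
  expect_equal(closure_g(dd, "kh"), exp(dd))
  # linear branch above zero
  du <- seq(0, 3, by = 0.25)
  expect_equal(closure_g(du, "kh"), 1 + du)
})

test_that("OZ with the identity kernel returns c unchanged", {
  set.seed(5)
  grid <- grid_spec(rep(0, 3), 1, 8L)
  cf <- list(X = array(rnorm(512), dim = c(8, 8, 8)))
  h <- oz_convolve(cf, identity_chi(), grid)
  expect_equal(h$X, cf$X, tolerance = 1e-12)
  # and c = 0 maps to h = 0
  h0 <- oz_convolve(list(X = array(0, dim = c(8, 8, 8))),
                    identity_chi(), grid)
  expect_true(all(h0$X == 0))
})

test_that("FFT convolution matches the direct O(N^2) periodic sum", {
  set.seed(6)
  n <- 8L
  grid <- grid_spec(rep(0, 3), 1, n)
  cf <- array(rnorm(n^3), dim = rep(n, 3))
  # synthetic smooth radial susceptibility
  k <- seq(0.001, 50, length.out = 200)
  chival <- 1 + 0.5 * exp(-k^2 / 4)
  chi <- list(k = k,
              chi = matrix(stats::approx(k, chival, k)$y, ncol = 1,
                           dimnames = list(NULL, "X:X")),
              site_table = data.frame(type = "X", multiplicity = 1L,
                                      charge = 0, sigma = 0, epsilon = 0,
                                      rho_site = 0.03))
  h_fft <- oz_convolve(list(X = cf), chi, grid)$X
  # oracle: build the kernel on the lattice, convolve by brute force
  kk <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1)) * 2 * pi / n
  kmag <- sqrt(outer(outer(kk^2, kk^2, "+"), kk^2, "+"))
  chi_lat <- array(stats::approx(k, chival, as.numeric(kmag), rule = 2)$y,
                   dim = rep(n, 3))
  kern <- Re(fft(chi_lat, inverse = TRUE)) / n^3
  h_direct <- array(0, dim = rep(n, 3))
  for (i in 0:(n - 1)) for (j in 0:(n - 1)) for (l in 0:(n - 1)) {
    acc <- 0
    for (a in 0:(n - 1)) for (b in 0:(n - 1)) for (cc in 0:(n - 1)) {
      acc <- acc + cf[a + 1, b + 1, cc + 1] *
        kern[(i - a) %% n + 1, (j - b) %% n + 1, (l - cc) %% n + 1]
    }
    h_direct[i + 1, j + 1, l + 1] <- acc
  }
  expect_lt(max(abs(h_fft - h_direct)) / max(abs(h_direct)), 1e-10)
})

test_that("a short susceptibility k-range is refused", {
  grid <- grid_spec(rep(0, 3), 0.5, 8L)
  chi <- identity_chi(kmax = 2)   # Nyquist of this grid is ~2 pi
  expect_error(oz_convolve(list(X = array(0, dim = rep(8, 3))), chi, grid),
               "k-range")
})
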