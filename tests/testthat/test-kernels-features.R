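test_that("first-order Green's function satisfies its defining properties", {
  g <- greens_first_order(2)
  expect_equal(greens_eval(g, 0), 1)
  expect_equal(greens_eval(greens_first_order(1), 1), exp(-1))
  # unit impulse mass 1/gamma (numeric area over [0, T] as T grows)
  area <- stats::integrate(function(x) greens_eval(g, x), 0, 50)$value
  expect_equal(area, 0.5, tolerance = 1e-8)
  expect_error(greens_first_order(-1))
  # strictly decreasing on x >= 0
  xs <- seq(0, 5, 0.5)
  expect_true(all(diff(greens_eval(g, xs)) < 0))
})

test_that("complex response features match their defining integral", {
  expect_equal(rfrf_complex(0, 1, 3), 0 + 0i)
  expect_equal(Re(rfrf_complex(1, 1, 0)), 1 - exp(-1), tolerance = 1e-12)
  # quadrature oracle at a non-trivial point
  q <- rfrf_quadrature(2, 1, pi)
  expect_equal(rfrf_complex(2, 1, pi), q, tolerance = 1e-8)
})

test_that("response features are conjugate-symmetric in the frequency", {
  set.seed(1)
  t <- runif(20, 0, 10); g <- runif(20, 0.1, 5); w <- rnorm(20, sd = 3)
  expect_equal(rfrf_complex(t, g, -w), Conj(rfrf_complex(t, g, w)))
})

test_that("realification preserves inner products and ordering", {
  expect_equal(rfrf_realify(1 + 2i), c(1, 2))
  expect_equal(rfrf_realify(complex(real = c(0, 0), imaginary = c(0, 0))),
               rep(0, 4))
  set.seed(2)
  a <- complex(real = rnorm(7), imaginary = rnorm(7))
  b <- complex(real = rnorm(7), imaginary = rnorm(7))
  expect_equal(sum(rfrf_realify(a) * rfrf_realify(b)),
               Re(sum(a * Conj(b))))
})

test_that("multi-dimensional features sum per-dimension responses", {
  om <- list(matrix(c(0.3, -1, 2), 1))
  one <- rfrf_multidim(matrix(1.2), gamma = 0.7, omega = om, sensitivity = 1)
  expect_equal(drop(one),
               sqrt(1 / 3) * rfrf_complex(1.2, 0.7, c(0.3, -1, 2)))
  # zero input -> zero vector
  expect_equal(drop(rfrf_multidim(matrix(0), 0.7, om, 1)), rep(0 + 0i, 3))
  # p = 2 with equal coordinates and shared blocks doubles the p = 1 result
  om2 <- list(om[[1]], om[[1]])
  two <- rfrf_multidim(matrix(c(1.2, 1.2), 1), c(0.7, 0.7), om2, 1)
  expect_equal(drop(two), 2 * drop(one))
  expect_error(rfrf_multidim(matrix(c(1, 2), 1), 0.7, om, 1))
})

test_that("EQ random Fourier features follow the baseline definition", {
  om <- matrix(rnorm(10), 1)
  z <- eq_rff(matrix(0), om, variance = 2)
  expect_equal(drop(z), sqrt(2 / 10) * c(rep(1, 10), rep(0, 10)))
  expect_equal(eq_rff(matrix(1.3), om, variance = 0),
               matrix(0, 1, 20))
  # MC convergence of the kernel estimate at N_RF = 500
  set.seed(3)
  x <- matrix(c(0.2, 0.9), 2)
  est <- mean(replicate(50, {
    omr <- matrix(rnorm(500, sd = sqrt(2) / 0.8), 1)
    ph <- eq_rff(x, omr, variance = 1)
    (ph %*% t(ph))[1, 2]
  }))
  expect_equal(est, exp(-(0.7)^2 / 0.8^2), tolerance = 0.05)
})

test_that("spectral sampling follows the kernel's frequency law", {
  k <- latent_force_kernel(lengthscale = c(0.5, 2), variance = 1, q = 2)
  om <- sample_spectral(k, n_rf = 4000, seed = 1)
  expect_equal(dim(om), c(2, 4000))
  expect_equal(apply(om, 1, sd), sqrt(2) / c(0.5, 2), tolerance = 0.05)
  # fixed per seed
  expect_identical(om, sample_spectral(k, 4000, seed = 1))
  # n_rf = 1 keeps the q x n_rf orientation
  expect_equal(dim(sample_spectral(k, 1, seed = 1)), c(2, 1))
})

test_that("feature covariance estimate agrees with the double-integral oracle", {
  k <- latent_force_kernel(lengthscale = 1, variance = 1, q = 1)
  oracle <- lfm_kernel_quadrature(2, 3, gamma_d = 1, gamma_dp = 1,
                                  kernel = k, sens_d = 1, sens_dp = 1)
  set.seed(4)
  est <- mean(replicate(30, {
    om <- list(sample_spectral(k, 200))
    p1 <- rfrf_multidim(matrix(2), 1, om, 1)
    p2 <- rfrf_multidim(matrix(3), 1, om, 1)
    Re(sum(p1 * Conj(p2)))
  }))
  expect_equal(est, oracle, tolerance = 0.05)
})

test_that("scaled complementary error function is accurate at both branches", {
  x <- c(0, 1, 24.9, 25.1, 100, 1000)
  expect_equal(erfcx(0), 1)
  # against the defining product where it is representable
  expect_equal(erfcx(x[1:3]), exp(x[1:3]^2) * pracma::erfc(x[1:3]))
  # asymptotic branch continuous with the direct branch
  expect_equal(erfcx(25.0000001), erfcx(24.9999999), tolerance = 1e-6)
  # large-x law ~ 1/(x sqrt(pi))
  expect_equal(erfcx(1000) * 1000 * sqrt(pi), 1, tolerance = 1e-6)
})

test_that("softplus bijection round-trips and stays positive", {
  x <- c(-10, -1, 0, 1, 10, 50)
  expect_true(all(softplus(x) > 0))
  expect_equal(softplus_inv(softplus(x)), x)
  expect_error(softplus_inv(-1))
})
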