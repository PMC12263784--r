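test_that("cosine convolution matches its quadrature oracle", {
  expect_equal(conv_cosine(2, 0, 0, 1), 0.5)
  expect_equal(conv_cosine(1, 1, 0, 0), 0.5)
  for (g in c(0.1, 1, 10)) {
    for (th in c(0.5, 4)) {
      got <- conv_cosine(g, th, 0.3, 1.7)
      want <- conv_cosine_quadrature(g, th, 0.3, 1.7)
      expect_equal(got, want, tolerance = 1e-9)
    }
  }
  expect_error(conv_cosine(-1, 1, 0, 1))
})

test_that("canonical convolution matches its quadrature oracle", {
  for (g in c(0.1, 1, 50)) {
    for (ell in c(0.05, 1)) {
      got <- conv_eq_canonical(g, ell, x = 0.8, z_m = 0.5)
      want <- conv_eq_quadrature(g, ell, x = 0.8, z_m = 0.5)
      expect_equal(got, want, tolerance = 1e-9)
    }
  }
  # large gamma*ell product: the erfcx branch must not overflow
  big <- conv_eq_canonical(500, 1, x = 0.5, z_m = 0.2)
  expect_true(is.finite(big) && big > 0)
  expect_error(conv_eq_canonical(1, -1, 1, 0))
})

test_that("both convolutions satisfy the defining first-order ODE", {
  # d/dx int_{-inf}^x e^{-gamma(x-z)} b(z) dz = b(x) - gamma * C(x)
  h <- 1e-6
  g <- 1.3; th <- 2.1; be <- 0.4; x <- 0.9
  lhs <- (conv_cosine(g, th, be, x + h) - conv_cosine(g, th, be, x - h)) / (2 * h)
  expect_equal(lhs, cos(th * x + be) - g * conv_cosine(g, th, be, x),
               tolerance = 1e-7)
  ell <- 0.3; zm <- 0.5
  lhs2 <- (conv_eq_canonical(g, ell, x + h, zm) -
             conv_eq_canonical(g, ell, x - h, zm)) / (2 * h)
  expect_equal(lhs2, exp(-(x - zm)^2 / ell^2) -
                 g * conv_eq_canonical(g, ell, x, zm), tolerance = 1e-7)
})

test_that("canonical convolution derivatives match central differences", {
  h <- 1e-6
  for (cfg in list(c(0.5, 0.2, 0.7, 0.3), c(3, 1.5, -0.4, 0.9))) {
    g <- cfg[1]; ell <- cfg[2]; x <- cfg[3]; zm <- cfg[4]
    gr <- dlfm:::conv_eq_grads(g, ell, x, zm)
    expect_equal(gr$dgamma,
                 (conv_eq_canonical(g + h, ell, x, zm) -
                    conv_eq_canonical(g - h, ell, x, zm)) / (2 * h),
                 tolerance = 1e-6)
    expect_equal(gr$dell,
                 (conv_eq_canonical(g, ell + h, x, zm) -
                    conv_eq_canonical(g, ell - h, x, zm)) / (2 * h),
                 tolerance = 1e-6)
    expect_equal(gr$dx,
                 (conv_eq_canonical(g, ell, x + h, zm) -
                    conv_eq_canonical(g, ell, x - h, zm)) / (2 * h),
                 tolerance = 1e-6)
  }
})

test_that("KL divergences vanish exactly when q equals p", {
  expect_equal(kl_gaussian(0, 1, 0, 1), 0)
  expect_equal(kl_gaussian(1, 1, 0, 1), 0.5)
  expect_true(kl_gaussian(0.3, 2, 0, 1) > 0)
  set.seed(5)
  A <- crossprod(matrix(rnorm(25), 5)) + diag(5)
  expect_equal(kl_mvn(rep(0, 5), A, A), 0, tolerance = 1e-10)
  expect_true(kl_mvn(rnorm(5), A, A + diag(5)) > 0)
})
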