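test_that("normalised MSE uses the population variance of the targets", {
  expect_equal(nmse(c(0, 2), c(1, 1)), 1)
  expect_equal(nmse(c(0, 2), c(0, 2)), 0)
  # NA targets are excluded
  expect_equal(nmse(c(0, 2, NA), c(1, 1, 99)), 1)
  expect_error(nmse(c(NA, NA), c(1, 1)))
})

test_that("RMSE and MNLL take their textbook values", {
  expect_equal(rmse(c(0, 0), c(3, 4)), sqrt(12.5))
  expect_equal(mnll(0, 0, 1), 0.5 * log(2 * pi))
  expect_equal(mnll(c(1, NA), c(1, 0), c(2, 2)), 0.5 * log(4 * pi))
  expect_error(mnll(0, 0, -1))
})

test_that("predictive summaries expose exact sample statistics and bands", {
  sams <- array(rnorm(5 * 4 * 2), dim = c(5, 4, 2))
  ps <- dlfm:::new_predictive_summary(sams, sigma2_y_orig = c(0.1, 0.4))
  expect_equal(ps$mean, apply(sams, c(2, 3), mean))
  expect_equal(ps$var, sweep(apply(sams, c(2, 3), var), 2, c(0.1, 0.4), "+"))
  expect_equal(ps$upper, ps$mean + 2 * ps$sd)
  expect_equal(ps$lower, ps$mean - 2 * ps$sd)
})

test_that("fitting improves the variational bound and predicts on data scale", {
  set.seed(1)
  t <- seq(0, 5, length.out = 60)
  y <- cbind(10 + 3 * sin(2 * t))
  m <- fit(dlfm_rff(1, 1, n_layers = 2, n_rf = 20, seed = 1), matrix(t), y,
           iterations = 400, lr = 0.02, seed = 1)
  tr <- m$fit_report$trace
  expect_gt(tail(tr$elbo, 1), tr$elbo[1])
  ps <- predict(m, matrix(t), n_samples = 30, seed = 2)
  # predictions come back on the original (unstandardised) scale
  expect_lt(rmse(y, ps$mean), 1.5)
  expect_gt(mean(ps$mean), 8)
  expect_lt(nmse(y, ps$mean), 0.3)
})

test_that("fitting handles missing targets and reports a reproducible trace", {
  set.seed(2)
  t <- seq(0, 5, length.out = 50)
  y <- cbind(sin(t), cos(t))
  y[10:20, 1] <- NA
  m1 <- fit(dlfm_vip(1, 2, n_layers = 1, m_inducing = 10, b_basis = 32,
                     seed = 1), matrix(t), y, iterations = 150, seed = 3)
  m2 <- fit(dlfm_vip(1, 2, n_layers = 1, m_inducing = 10, b_basis = 32,
                     seed = 1), matrix(t), y, iterations = 150, seed = 3)
  expect_identical(m1$fit_report$trace, m2$fit_report$trace)
  ps <- predict(m1, matrix(t), n_samples = 20, seed = 1)
  expect_true(all(is.finite(ps$mean)))
})

test_that("evaluate_predictions bundles the three study metrics", {
  sams <- array(rep(c(1, 2), each = 3), dim = c(3, 1, 2))
  ps <- dlfm:::new_predictive_summary(sams, c(0.5, 0.5))
  out <- evaluate_predictions(ps, matrix(c(1, 2), 1, 2))
  expect_equal(out$rmse, 0)
  expect_equal(out$mnll, 0.5 * log(2 * pi * 0.5))
})
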