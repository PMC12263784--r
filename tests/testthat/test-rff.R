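test_that("frequency draws follow the fixed-noise variational contract", {
  m <- dlfm_rff(2, 2, n_layers = 2, n_rf = 5, q = 2, seed = 7)
  d1 <- sample_variational(m, sample_w = FALSE)
  d2 <- sample_variational(m, sample_w = FALSE)
  # frequencies are a deterministic function of the variational parameters
  expect_identical(d1[[1]][[1]]$Omega, d2[[1]][[1]]$Omega)
  # shifting the mean shifts the realisation by exactly that amount
  m2 <- m
  m2$layers[[1]]$blocks[[1]]$params$m_omega <-
    m2$layers[[1]]$blocks[[1]]$params$m_omega + 0.5
  d3 <- sample_variational(m2, sample_w = FALSE)
  expect_equal(d3[[1]][[1]]$Omega, d1[[1]][[1]]$Omega + 0.5)
  # weight sampling is seeded
  expect_identical(sample_variational(m, seed = 3), sample_variational(m, seed = 3))
})

test_that("layer samples at the zero input equal the bias exactly", {
  m <- dlfm_rff(3, 4, n_layers = 1, n_rf = 8, q = 2,
                per_output_final = FALSE, seed = 2)
  block <- m$layers[[1]]$blocks[[1]]
  block$params$c <- c(0.3, -1, 2, 0.25)
  dr <- sample_variational(m, seed = 9)[[1]][[1]]
  out <- layer_forward(matrix(0, 2, 3), block, dr$Omega, dr$W)
  expect_identical(out[1, ], c(0.3, -1, 2, 0.25))
  expect_identical(out[2, ], c(0.3, -1, 2, 0.25))
})

test_that("per-output final layers give each output its own block", {
  m <- dlfm_rff(1, 3, n_layers = 2, n_rf = 6, seed = 4)
  expect_length(m$layers[[2]]$blocks, 3)
  draws <- sample_variational(m, seed = 1)
  fin <- matrix(c(0.5, 1, 0.2, 0.4, 0.3, 0.1), 2, 3)
  out <- final_layer_per_output(fin, m$layers[[2]]$blocks, draws[[2]])
  expect_equal(dim(out), c(2, 3))
})

test_that("weight-space bound gradients match finite differences", {
  set.seed(11)
  m <- dlfm_rff(2, 2, n_layers = 2, n_rf = 3, q = 2, sigma2_y = 0.2, seed = 5)
  p <- dlfm:::rff_params(m)
  fl <- dlfm:::flatten_params(p) + 0.1 * rnorm(length(dlfm:::flatten_params(p)))
  m <- dlfm:::rff_set_params(m, dlfm:::unflatten_params(fl, p))
  x <- matrix(runif(8), 4, 2)
  y <- matrix(rnorm(8), 4, 2); y[2, 1] <- NA
  for (local in c(FALSE, TRUE)) {
    ev <- elbo_rff(m, x, y, n_total = 10, n_mc = 2, seed = 42, local = local,
                   compute_grad = TRUE)
    ga <- dlfm:::flatten_params(ev$grads)
    h <- 1e-5
    idx <- seq(1, length(fl), length.out = 25)
    for (i in unique(round(idx))) {
      fp <- fl; fp[i] <- fp[i] + h
      fm <- fl; fm[i] <- fm[i] - h
      gn <- (elbo_rff(dlfm:::rff_set_params(m, dlfm:::unflatten_params(fp, p)),
                      x, y, n_total = 10, n_mc = 2, seed = 42,
                      local = local)$value -
               elbo_rff(dlfm:::rff_set_params(m, dlfm:::unflatten_params(fm, p)),
                        x, y, n_total = 10, n_mc = 2, seed = 42,
                        local = local)$value) / (2 * h)
      expect_equal(ga[i], gn, tolerance = 1e-4)
    }
  }
})

test_that("weight-space KL vanishes when the posterior equals the prior", {
  m <- dlfm_rff(1, 1, n_layers = 2, n_rf = 4, seed = 3)
  for (l in seq_along(m$layers)) {
    for (b in seq_along(m$layers[[l]]$blocks)) {
      pp <- m$layers[[l]]$blocks[[b]]$params
      ell <- dlfm:::softplus(pp$rho_ell)
      pp$m_w[] <- 0
      pp$rho_s_w[] <- dlfm:::softplus_inv(1)
      pp$m_omega[] <- 0
      pp$rho_s_omega[] <- dlfm:::softplus_inv(sqrt(2) / ell[1])
      m$layers[[l]]$blocks[[b]]$params <- pp
    }
  }
  kl <- dlfm:::rff_kl_terms(m, compute_grad = FALSE)
  expect_equal(kl$value, 0, tolerance = 1e-12)
})

test_that("likelihood of one perfectly predicted datum is the Gaussian constant", {
  m <- dlfm_rff(1, 1, n_layers = 1, n_rf = 4, sigma2_y = 0.3, seed = 6)
  # zero input gives output exactly c; set the target to c
  cc <- 0.7
  m$layers[[1]]$blocks[[1]]$params$c <- cc
  ev <- elbo_rff(m, matrix(0), matrix(cc), n_total = 1, n_mc = 1, seed = 1)
  sigma2 <- dlfm:::softplus(m$rho_sigma2_y)
  expect_equal(ev$loglik, -0.5 * log(2 * pi * sigma2), tolerance = 1e-12)
})

test_that("minibatch scaling keeps the likelihood term unbiased", {
  set.seed(8)
  m <- dlfm_rff(1, 1, n_layers = 2, n_rf = 5, seed = 2)
  x <- matrix(seq(0, 1, length.out = 40))
  y <- matrix(sin(6 * x))
  full <- elbo_rff(m, x, y, n_total = 40, seed = 1, local = FALSE)$loglik
  # average the scaled minibatch term over random batches (the draw seed is
  # fixed, so the only randomness is the batch choice)
  batch_vals <- replicate(300, {
    idx <- sample.int(40, 10)
    elbo_rff(m, x[idx, , drop = FALSE], y[idx, , drop = FALSE],
             n_total = 40, seed = 1, local = FALSE)$loglik
  })
  se <- sd(batch_vals) / sqrt(length(batch_vals))
  expect_lt(abs(mean(batch_vals) - full), 4 * se + 1e-8)
})
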