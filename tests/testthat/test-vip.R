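test_that("pathwise latent samples interpolate their inducing outputs", {
  m <- dlfm_vip(1, 2, n_layers = 2, q = 2, m_inducing = 15, b_basis = 32,
                seed = 4)
  for (l in 1:2) {
    for (qi in 1:2) {
      ls <- vip_latent_sample(m, layer = l, force = qi, seed = 10 * l + qi)
      z <- m$layers[[l]]$forces[[qi]]$z
      expect_lt(max(abs(ls$fn(z) - ls$v)), 1e-8)
    }
  }
})

test_that("zero inducing points give pure prior paths with EQ moments", {
  m <- dlfm_vip(1, 1, n_layers = 1, m_inducing = 0, b_basis = 512, seed = 3)
  xs <- matrix(c(0.1, 0.4, 0.8))
  set.seed(21)
  draws <- sapply(1:800, function(s) vip_latent_sample(m, seed = s)$fn(xs))
  ell <- dlfm:::softplus(m$layers[[1]]$forces[[1]]$rho_ell)
  expect_equal(rowMeans(draws), rep(0, 3), tolerance = 0.12)
  emp <- cov(t(draws))
  expect_equal(emp[1, 2], eq_kernel(0.1, 0.4, ell)[1, 1], tolerance = 0.12)
  expect_equal(diag(emp), rep(1, 3), tolerance = 0.15)
})

test_that("layer outputs at the origin are not pinned to a constant", {
  m <- dlfm_vip(1, 2, n_layers = 1, m_inducing = 10, b_basis = 64, seed = 6)
  at0 <- sapply(1:60, function(s) {
    vip_output_sample(m, matrix(0), layer = 1, seed = s)[1, ]
  })
  expect_gt(min(apply(at0, 1, sd)), 0.05)
})

test_that("inducing-point bound gradients match finite differences", {
  set.seed(31)
  m <- dlfm_vip(2, 2, n_layers = 2, hidden_width = 2, q = 2, m_inducing = 4,
                b_basis = 3, seed = 3)
  p <- dlfm:::vip_params(m)
  fl <- dlfm:::flatten_params(p) + 0.1 * rnorm(length(dlfm:::flatten_params(p)))
  m <- dlfm:::vip_set_params(m, dlfm:::unflatten_params(fl, p))
  x <- matrix(runif(8), 4, 2)
  y <- matrix(rnorm(8), 4, 2); y[3, 2] <- NA
  ev <- elbo_vip(m, x, y, n_total = 9, n_samples = 2, seed = 13,
                 compute_grad = TRUE)
  ga <- dlfm:::flatten_params(ev$grads)
  h <- 1e-5
  for (i in unique(round(seq(1, length(fl), length.out = 30)))) {
    fp <- fl; fp[i] <- fp[i] + h
    fm <- fl; fm[i] <- fm[i] - h
    gn <- (elbo_vip(dlfm:::vip_set_params(m, dlfm:::unflatten_params(fp, p)),
                    x, y, n_total = 9, n_samples = 2, seed = 13)$value -
             elbo_vip(dlfm:::vip_set_params(m, dlfm:::unflatten_params(fm, p)),
                      x, y, n_total = 9, n_samples = 2, seed = 13)$value) /
      (2 * h)
    expect_equal(ga[i], gn, tolerance = 1e-4)
  }
})

test_that("inducing-point KL vanishes when the posterior equals the prior", {
  m <- dlfm_vip(1, 1, n_layers = 2, m_inducing = 8, b_basis = 16, seed = 9)
  for (l in 1:2) {
    fo <- m$layers[[l]]$forces[[1]]
    real <- dlfm:::force_realise(fo, m$jitter)
    K <- real$K0 + real$jit * diag(real$M)
    L <- t(chol(K))
    fo$mu <- rep(0, real$M)
    fo$rho_Ldiag <- dlfm:::softplus_inv(diag(L))
    fo$L_off <- L[lower.tri(L)]
    m$layers[[l]]$forces[[1]] <- fo
  }
  reals <- lapply(m$layers, function(lay) {
    lapply(lay$forces, dlfm:::force_realise, jitter = m$jitter)
  })
  kl <- dlfm:::vip_kl_terms(m, reals, compute_grad = FALSE)
  expect_equal(kl$value, 0, tolerance = 1e-9)
})

test_that("basis resampling toggle fixes the prior path across samples", {
  m <- dlfm_vip(1, 1, n_layers = 1, m_inducing = 0, b_basis = 16,
                resample_basis = FALSE, seed = 5)
  d <- dlfm:::vip_draws(m, 2, seed = 8)
  expect_identical(d[[1]][[1]][[1]]$eps_theta, d[[2]][[1]][[1]]$eps_theta)
  m2 <- dlfm_vip(1, 1, n_layers = 1, m_inducing = 0, b_basis = 16,
                 resample_basis = TRUE, seed = 5)
  d2 <- dlfm:::vip_draws(m2, 2, seed = 8)
  expect_false(identical(d2[[1]][[1]][[1]]$eps_theta,
                         d2[[2]][[1]][[1]]$eps_theta))
})

test_that("per-iteration cost grows superlinearly in the inducing count", {
  # complexity contract sanity check (non-binding on exact exponents):
  # doubling M must not scale the bound evaluation worse than ~M^3 and the
  # evaluation must stay well under a second at experiment scale
  x <- matrix(seq(0, 1, length.out = 64))
  y <- matrix(sin(6 * x))
  tm <- sapply(c(16, 64), function(M) {
    m <- dlfm_vip(1, 1, n_layers = 1, m_inducing = M, b_basis = 32, seed = 2)
    system.time(for (r in 1:5) elbo_vip(m, x, y, n_samples = 1, seed = r,
                                        compute_grad = TRUE))[3]
  })
  expect_lt(tm[2], 5)
})
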