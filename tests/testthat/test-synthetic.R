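test_that("toy system closed form agrees with adaptive quadrature", {
  sp <- toy_system_spec(n_steps = 40)
  d <- simulate_toy(sp)
  spq <- toy_system_spec(harmonics = NULL,
                         u_fun = function(t) cos(0.5 * t) + 6 * sin(3 * t),
                         n_steps = 40)
  dq <- simulate_toy(spq)
  expect_lt(max(abs(d$f1 - dq$f1)), 1e-8)
  expect_lt(max(abs(d$f2 - dq$f2)), 1e-8)
  # first stage starts at the empty integration interval
  expect_equal(d$f1[1], 0)
  # the second stage is probed at negative upper limits too
  expect_lt(min(d$f1), 0)
})

test_that("toy observation noise behaves as specified", {
  d0 <- simulate_toy(toy_system_spec(noise_sd = 0, n_steps = 50))
  expect_identical(d0$y2, d0$f2)
  d1 <- simulate_toy(toy_system_spec(n_steps = 200, seed = 5))
  d2 <- simulate_toy(toy_system_spec(n_steps = 200, seed = 5))
  expect_identical(d1, d2)
  # default noise level: 5% of the signal's standard deviation
  expect_equal(sd(d1$y2 - d1$f2), 0.05 * sd(d1$f2), tolerance = 0.15)
})

test_that("multi-output generator is a pure function of its seed", {
  a <- simulate_charis_like(n_steps = 120, seed = 9)
  b <- simulate_charis_like(n_steps = 120, seed = 9)
  expect_identical(a, b)
  c3 <- simulate_charis_like(n_steps = 120, seed = 10)
  expect_false(identical(a$data, c3$data))
})

test_that("shared latents induce stronger cross-output correlation", {
  set.seed(1)
  cor_shared <- numeric(50); cor_indep <- numeric(50)
  for (s in 1:50) {
    sh <- simulate_charis_like(n_steps = 100, seed = s)
    ind <- simulate_charis_like(n_steps = 100, seed = s,
                                shared_latents = FALSE)
    cs <- cor(sh$f); ci <- cor(ind$f)
    cor_shared[s] <- mean(abs(cs[upper.tri(cs)]))
    cor_indep[s] <- mean(abs(ci[upper.tri(ci)]))
  }
  expect_gt(mean(cor_shared), mean(cor_indep))
})

test_that("hidden-channel variance matches the analytic prior variance", {
  set.seed(2)
  vals <- sapply(1:150, function(s) {
    sim <- simulate_charis_like(n_steps = 100, seed = s)
    sim$hidden[80, ]
  })
  ana <- rowMeans(sapply(1:150, function(s) {
    simulate_charis_like(n_steps = 100, seed = s)$hidden_var
  }))
  emp <- apply(vals, 1, var)
  # 3 MC standard errors of a variance estimate from n draws
  se <- emp * sqrt(2 / (150 - 1))
  expect_true(all(abs(emp - ana) < 3 * se + 0.05))
})

test_that("imputation splits remove interior non-overlapping blocks", {
  m <- make_split(1000, 3, split_spec("imputation", 150, 1, seed = 3))
  expect_equal(colSums(m), rep(150, 3))
  for (d in 1:3) {
    runs <- rle(m[, d])
    expect_equal(sum(runs$lengths[runs$values]), 150)
    expect_false(m[1, d]); expect_false(m[1000, d])
  }
  # several blocks stay non-overlapping and of exact total length
  m8 <- make_split(500, 1, split_spec("imputation", 10, 8, seed = 1))
  expect_equal(sum(m8), 80)
  expect_equal(unique(rle(m8[, 1])$lengths[rle(m8[, 1])$values]), 10)
})

test_that("extrapolation splits hold out everything past the boundary", {
  m <- make_split(1000, 2, split_spec("extrapolation", boundary = 975))
  expect_equal(colSums(m), rep(25, 2))
  expect_true(all(m[976:1000, ]))
  expect_error(make_split(100, 1, split_spec("extrapolation", boundary = 100)))
})

test_that("infeasible split geometry errors out", {
  expect_error(make_split(100, 1, split_spec("imputation", 150)),
               "test points")
  y <- matrix(rnorm(20), 10, 2)
  msk <- make_split(10, 2, split_spec("random", 2, 1, seed = 1))
  ytr <- apply_split(y, msk)
  expect_equal(sum(is.na(ytr)), 4)
  expect_equal(y[!msk], ytr[!msk])
})
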