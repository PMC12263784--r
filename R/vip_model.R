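#' Deep latent force model with variational inducing points
#'
#' Builds the inducing-point formulation of the deep latent force model.
#' Each layer carries `q` latent EQ Gaussian processes summarised by `m`
#' inducing points with a full-covariance variational Gaussian over the
#' inducing outputs. Layer outputs are generated by pathwise (Matheron-rule)
#' sampling: a random-Fourier prior path plus a canonical update through
#' \eqn{K^{-1}}, mapped analytically through the whole-history convolution
#' \eqn{f_d(x) = \sum_q a_{d,q} \int_{-\infty}^{x} \prod_p
#' e^{-\gamma_{d,p}(x_p - z_p)}\, u_q(z)\, dz} using the closed forms
#' [conv_cosine()] and [conv_eq_canonical()]. Because the convolution runs
#' over the whole history rather than from the origin, samples near zero are
#' not pinned to an initial condition.
#'
#' @param d_in,d_out input and output dimensions of the data.
#' @param n_layers number of layers.
#' @param hidden_width width of hidden layers (defaults to `d_out`).
#' @param q latent forces per layer.
#' @param m_inducing inducing points per latent force (0 = pure prior, no
#'   variational update).
#' @param b_basis number of random Fourier basis functions per pathwise
#'   prior sample.
#' @param x_range numeric length-2, range of the (scaled) inputs over which
#'   first-layer inducing inputs are spread evenly.
#' @param inner_range range for inner-layer inducing inputs.
#' @param lengthscale initial latent lengthscale(s); default twice the
#'   inducing spacing.
#' @param gamma initial decay of every output filter.
#' @param sigma2_y initial likelihood noise variance.
#' @param jitter starting jitter added to inducing covariances (escalated
#'   1e2-fold up to 1e-4 on factorisation failure).
#' @param resample_basis redraw the pathwise basis frequencies for every
#'   sample (default) or fix them per model instance.
#' @param seed integer seed for initialisation draws.
#' @return an object of class `dlfm_vip` (also `dlfm_model`).
#' @export
dlfm_vip <- function(d_in, d_out, n_layers = 2, hidden_width = d_out,
                     q = 1, m_inducing = 20, b_basis = 256,
                     x_range = c(0, 1), inner_range = c(-2, 2),
                     lengthscale = NULL, gamma = 1, sigma2_y = 0.1,
                     jitter = 1e-8, resample_basis = TRUE, seed = 1) {
  stopifnot(d_in >= 1, d_out >= 1, n_layers >= 1, q >= 1, m_inducing >= 0,
            b_basis >= 1, sigma2_y > 0)
  widths <- c(d_in, rep(hidden_width, n_layers - 1), d_out)
  layers <- vector("list", n_layers)
  for (l in seq_len(n_layers)) {
    P <- widths[l]; D <- widths[l + 1]
    rng <- if (l == 1) x_range else inner_range
    span <- diff(rng)
    ell0 <- if (is.null(lengthscale)) {
      if (m_inducing > 1) 2 * span / (m_inducing - 1) else span / 2
    } else lengthscale
    forces <- vector("list", q)
    for (qi in seq_len(q)) {
      z <- inducing_grid(m_inducing, P, rng,
                         seed = derive_seed(seed, l * 977 + qi))
      M <- m_inducing
      forces[[qi]] <- list(
        z = z,
        mu = numeric(M),
        rho_Ldiag = rep(softplus_inv(0.1), M),
        L_off = numeric(max(M * (M - 1) / 2, 0)),
        rho_ell = softplus_inv(ell0))
    }
    # self-normalising mixing weights: the whole-history convolution of a
    # unit EQ process has marginal variance prod_p sqrt(pi) ell / (2 gamma)
    # * erfcx(gamma ell / 2), so dividing by its square root gives layer
    # outputs of order one at initialisation
    v_conv <- prod(rep(sqrt(pi) * ell0 / (2 * gamma) *
                         erfcx(gamma * ell0 / 2), length.out = P))
    a0 <- with_seed(derive_seed(seed, l * 13 + 7),
                    matrix(1 + 0.05 * stats::rnorm(D * q), D, q))
    a0 <- a0 / sqrt(q * v_conv)
    # hidden layers: start the first latent force on a centred linear ramp
    # in its inducing inputs, so the initial layer map is monotone rather
    # than constant (avoids the flat-inner-layer deadlock of deep GP
    # optimisation); remaining forces start at zero mean
    if (l < n_layers && m_inducing > 1) {
      z1 <- forces[[1]]$z[, 1]
      forces[[1]]$mu <- 6 * (z1 - mean(z1)) / (diff(range(z1)) + 1e-12)
    }
    layers[[l]] <- list(P = P, D = D, Q = q, M = m_inducing, B = b_basis,
                        forces = forces,
                        a = a0,
                        rho_gamma = matrix(softplus_inv(gamma), D, P))
  }
  model <- list(layers = layers, n_layers = n_layers,
                d_in = d_in, d_out = d_out,
                rho_sigma2_y = softplus_inv(sigma2_y),
                jitter = jitter,
                resample_basis = resample_basis,
                scaling = identity_scaling(d_in, d_out),
                seed = seed)
  if (!resample_basis) {
    model$fixed_basis <- with_seed(derive_seed(seed, 5077),
                                   vip_draw_eps(model))
  }
  class(model) <- c("dlfm_vip", "dlfm_model")
  model
}

# Evenly spread inducing inputs; one evenly spaced sequence per dimension,
# independently permuted for P > 1 (Latin-hypercube style) so points do not
# collapse onto a diagonal.
inducing_grid <- function(m, p, rng, seed = 1) {
  if (m == 0) return(matrix(numeric(0), 0, p))
  base <- seq(rng[1], rng[2], length.out = max(m, 2))[seq_len(m)]
  if (m > 1) base <- seq(rng[1], rng[2], length.out = m)
  z <- matrix(base, m, p)
  if (p > 1) {
    with_seed(seed, {
      for (j in 2:p) z[, j] <- sample(z[, j])
    })
  }
  z
}

# ---- parameter plumbing ----------------------------------------------------

vip_params <- function(model) {
  list(layers = lapply(model$layers, function(layer) {
    list(forces = lapply(layer$forces, function(fo) {
      list(mu = fo$mu, rho_Ldiag = fo$rho_Ldiag, L_off = fo$L_off,
           rho_ell = fo$rho_ell)
    }),
    a = layer$a, rho_gamma = layer$rho_gamma)
  }),
  rho_sigma2_y = model$rho_sigma2_y)
}

vip_set_params <- function(model, params) {
  for (l in seq_along(model$layers)) {
    for (qi in seq_along(model$layers[[l]]$forces)) {
      fp <- params$layers[[l]]$forces[[qi]]
      model$layers[[l]]$forces[[qi]]$mu <- fp$mu
      model$layers[[l]]$forces[[qi]]$rho_Ldiag <- fp$rho_Ldiag
      model$layers[[l]]$forces[[qi]]$L_off <- fp$L_off
      model$layers[[l]]$forces[[qi]]$rho_ell <- fp$rho_ell
    }
    model$layers[[l]]$a <- params$layers[[l]]$a
    model$layers[[l]]$rho_gamma <- params$layers[[l]]$rho_gamma
  }
  model$rho_sigma2_y <- params$rho_sigma2_y
  model
}

# Lower-triangular factor from its packed parameterisation.
build_L <- function(rho_Ldiag, L_off) {
  M <- length(rho_Ldiag)
  L <- matrix(0, M, M)
  if (M > 1) L[lower.tri(L)] <- L_off
  diag(L) <- softplus(rho_Ldiag)
  L
}

# Constrained quantities of one latent force: lengthscale, chol factor of
# the (jittered) inducing covariance, variational factor. Jitter escalates
# 1e2-fold per failure up to 1e-4.
force_realise <- function(force, jitter) {
  ell <- softplus(force$rho_ell)
  M <- length(force$mu)
  out <- list(ell = ell, M = M, z = force$z, mu = force$mu)
  out$L <- build_L(force$rho_Ldiag, force$L_off)
  if (M > 0) {
    d2 <- as.matrix(stats::dist(force$z))^2
    K0 <- exp(-d2 / ell^2)
    j <- jitter
    repeat {
      ch <- tryCatch(chol(K0 + j * diag(M)), error = function(e) NULL)
      if (!is.null(ch)) break
      j <- j * 100
      if (j > 1e-4) stop("inducing covariance not factorisable at max jitter")
    }
    out$d2 <- d2
    out$K0 <- K0
    out$jit <- j
    out$cholK <- ch
  }
  out
}

chol_solve <- function(ch, b) {
  backsolve(ch, backsolve(ch, b, transpose = TRUE))
}

# alpha solving K0 alpha ~= r, preconditioned by the jittered factorisation
# with iterative refinement (drives the interpolation residual at the
# inducing inputs towards roundoff for well-conditioned K). Refinement stops
# when the residual reaches roundoff or stops shrinking, keeping the best
# iterate, so badly conditioned systems cannot diverge.
solve_update <- function(real, r, refine = 30L) {
  scale_r <- max(abs(r), 1)
  alpha <- chol_solve(real$cholK, r)
  res <- r - real$K0 %*% alpha
  best <- alpha
  best_norm <- max(abs(res))
  for (i in seq_len(refine)) {
    if (best_norm <= 1e-13 * scale_r) break
    alpha <- alpha + chol_solve(real$cholK, res)
    res <- r - real$K0 %*% alpha
    rn <- max(abs(res))
    if (rn < best_norm) {
      best <- alpha
      best_norm <- rn
    } else {
      break
    }
  }
  drop(best)
}

# ---- pathwise draws --------------------------------------------------------

# One set of standard draws for every layer/force: basis frequencies
# (standard normal, scaled by sqrt(2)/ell at use), phases, basis weights and
# the whitened inducing-output draw.
vip_draw_eps <- function(model) {
  lapply(model$layers, function(layer) {
    lapply(layer$forces, function(fo) {
      M <- length(fo$mu)
      list(eps_theta = matrix(stats::rnorm(layer$B * layer$P), layer$B, layer$P),
           beta = stats::runif(layer$B, 0, 2 * pi),
           w = stats::rnorm(layer$B),
           eta = stats::rnorm(M))
    })
  })
}

vip_draws <- function(model, n_samples, seed = NULL) {
  gen <- function() {
    lapply(seq_len(n_samples), function(s) {
      if (!model$resample_basis) {
        dr <- model$fixed_basis
        # inducing-output draw is still refreshed per sample
        for (l in seq_along(dr)) for (qi in seq_along(dr[[l]])) {
          dr[[l]][[qi]]$eta <- stats::rnorm(length(dr[[l]][[qi]]$eta))
        }
        dr
      } else {
        vip_draw_eps(model)
      }
    })
  }
  if (is.null(seed)) gen() else with_seed(seed, gen())
}

#' Pathwise sample of a latent force
#'
#' Realises one functional sample
#' \deqn{u^{(s)}(x) = \sum_i w_i \sqrt{2/B}\cos(\theta_i^\top x + \beta_i)
#'  + k(x, Z) K^{-1} (v - \Phi w)}
#' from a latent force of a layer and returns it as a function evaluable at
#' arbitrary points. Evaluating at the inducing inputs reproduces the
#' sampled inducing outputs (the Matheron interpolation contract). With zero
#' inducing points the update term vanishes and the result is a pure prior
#' sample.
#'
#' @param model a `dlfm_vip` model.
#' @param layer,force indices of the layer and latent force.
#' @param seed integer seed for the draws (ignored if `draw` supplied).
#' @param draw optionally, a draw list as produced internally (fields
#'   `eps_theta`, `beta`, `w`, `eta`).
#' @return list with `fn` (vectorised function of new inputs, matrix or
#'   vector), `v` (the sampled inducing outputs) and the realised draw.
#' @export
vip_latent_sample <- function(model, layer = 1, force = 1, seed = NULL,
                              draw = NULL) {
  stopifnot(inherits(model, "dlfm_vip"))
  lay <- model$layers[[layer]]
  fo <- lay$forces[[force]]
  real <- force_realise(fo, model$jitter)
  if (is.null(draw)) {
    draw <- if (is.null(seed)) vip_draw_eps(model)[[layer]][[force]] else
      with_seed(seed, vip_draw_eps(model)[[layer]][[force]])
  }
  theta <- draw$eps_theta * (sqrt(2) / real$ell)
  B <- lay$B
  M <- real$M
  if (M > 0) {
    v <- real$mu + drop(real$L %*% draw$eta)
    phi_z <- sqrt(2 / B) * cos(real$z %*% t(theta) +
                                 matrix(draw$beta, M, B, byrow = TRUE))
    alpha <- solve_update(real, v - drop(phi_z %*% draw$w))
  } else {
    v <- numeric(0)
    alpha <- numeric(0)
  }
  fn <- function(xnew) {
    xnew <- as.matrix(xnew)
    arg <- xnew %*% t(theta) + matrix(draw$beta, nrow(xnew), B, byrow = TRUE)
    u <- sqrt(2 / B) * drop(cos(arg) %*% draw$w)
    if (M > 0) {
      kx <- eq_kernel(xnew, real$z, lengthscale = real$ell)
      u <- u + drop(kx %*% alpha)
    }
    u
  }
  list(fn = fn, v = v, alpha = alpha, theta = theta, draw = draw, ell = real$ell)
}

# ---- layer forward ---------------------------------------------------------

# Forward pass of one layer for one sample. reals: list of force_realise
# results (computed once per objective call). draw: per-force draw list.
# Returns N x D outputs plus a cache for the backward pass.
vip_layer_forward <- function(layer, reals, X, draw, keep_cache = FALSE) {
  X <- as.matrix(X)
  N <- nrow(X); P <- layer$P; D <- layer$D; B <- layer$B
  stopifnot(ncol(X) == P)
  gamma <- softplus(layer$rho_gamma) # D x P
  f <- matrix(0, N, D)
  caches <- if (keep_cache) vector("list", layer$Q) else NULL
  for (qi in seq_len(layer$Q)) {
    real <- reals[[qi]]
    dr <- draw[[qi]]
    theta <- dr$eps_theta * (sqrt(2) / real$ell) # B x P
    argX <- X %*% t(theta) + matrix(dr$beta, N, B, byrow = TRUE)
    Cx <- cos(argX); Sx <- sin(argX)
    # complex denominators prod_p (gamma_dp + i theta_ip), D x B
    denom <- matrix(1 + 0i, D, B)
    for (p in seq_len(P)) {
      denom <- denom * t(outer(theta[, p], gamma[, p],
                               function(th, g) complex(real = g, imaginary = th)))
    }
    u <- sweep(1 / denom, 2, dr$w, "*") # D x B complex: w_i / denom_di
    cospart <- sqrt(2 / B) * (Cx %*% t(Re(u)) - Sx %*% t(Im(u))) # N x D
    M <- real$M
    if (M > 0) {
      v <- real$mu + drop(real$L %*% dr$eta)
      argZ <- real$z %*% t(theta) + matrix(dr$beta, M, B, byrow = TRUE)
      phi_z <- sqrt(2 / B) * cos(argZ)
      rvec <- v - drop(phi_z %*% dr$w)
      alpha <- solve_update(real, rvec)
      Ig <- vector("list", D)
      canpart <- matrix(0, N, D)
      for (d in seq_len(D)) {
        Ig[[d]] <- vector("list", P)
        Td <- matrix(1, N, M)
        for (p in seq_len(P)) {
          amat <- outer(X[, p], real$z[, p], "-")
          Ig[[d]][[p]] <- conv_eq_grads(gamma[d, p], real$ell, amat, 0)
          Td <- Td * Ig[[d]][[p]]$value
        }
        canpart[, d] <- Td %*% alpha
        Ig[[d]]$T <- Td
      }
      bracket <- cospart + canpart
    } else {
      v <- numeric(0); alpha <- numeric(0); rvec <- numeric(0)
      phi_z <- NULL; argZ <- NULL; Ig <- NULL
      bracket <- cospart
    }
    f <- f + bracket %*% diag(layer$a[, qi], nrow = D) # scale column d by a_dq
    if (keep_cache) {
      caches[[qi]] <- list(theta = theta, Cx = Cx, Sx = Sx, denom = denom,
                           u = u, cospart = cospart, bracket = bracket,
                           v = v, alpha = alpha, rvec = rvec,
                           phi_z = phi_z, argZ = argZ, Ig = Ig, real = real,
                           dr = dr)
    }
  }
  list(output = f, gamma = gamma, caches = caches, X = X)
}

#' Output sample of one inducing-point layer
#'
#' Draws one pathwise latent sample per force and maps it analytically
#' through the layer's exponential filters, returning the layer outputs at
#' the supplied inputs. Exact (quadrature-free) by construction.
#'
#' @param model a `dlfm_vip` model.
#' @param x input matrix for the layer.
#' @param layer layer index.
#' @param seed integer seed for the pathwise draws.
#' @return numeric matrix `nrow(x)` x `D`.
#' @export
vip_output_sample <- function(model, x, layer = 1, seed = NULL) {
  lay <- model$layers[[layer]]
  reals <- lapply(lay$forces, force_realise, jitter = model$jitter)
  draw <- if (is.null(seed)) vip_draw_eps(model)[[layer]] else
    with_seed(seed, vip_draw_eps(model)[[layer]])
  vip_layer_forward(lay, reals, x, draw)$output
}

#' Compose an inducing-point model over its layers
#'
#' Propagates `n_samples` independent pathwise samples through the layer
#' stack: the multi-output sample of layer \eqn{\ell} becomes the evaluation
#' points of layer \eqn{\ell+1}. Returns the per-layer sample tensors.
#'
#' @param model a `dlfm_vip` model.
#' @param x input matrix `n` x `d_in` (model scale).
#' @param n_samples number of end-to-end samples.
#' @param seed integer seed.
#' @return list with one element per layer, each an array
#'   `(n_samples, n, D_layer)`.
#' @export
vip_compose <- function(model, x, n_samples = 1, seed = NULL) {
  x <- as.matrix(x)
  draws <- vip_draws(model, n_samples, seed = seed)
  reals <- lapply(model$layers, function(lay) {
    lapply(lay$forces, force_realise, jitter = model$jitter)
  })
  out <- lapply(model$layers, function(lay) {
    array(0, dim = c(n_samples, nrow(x), lay$D))
  })
  for (s in seq_len(n_samples)) {
    cur <- x
    for (l in seq_len(model$n_layers)) {
      cur <- vip_layer_forward(model$layers[[l]], reals[[l]], cur,
                               draws[[s]][[l]])$output
      out[[l]][s, , ] <- cur
    }
  }
  out
}
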