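# Evidence lower bound of the inducing-point model and its analytic
# gradient. The likelihood term is estimated with pathwise samples of the
# latent forces mapped through the closed-form layer convolutions; the
# penalty is the sum of full-covariance Gaussian KL terms
# KL[N(mu_q, L_q L_q^T) || N(0, K_uu + jitter I)] over every latent force.

#' Stochastic variational bound of the inducing-point model
#'
#' Evaluates the minibatch bound
#' \deqn{\frac{N}{M}\sum_{k \in batch}\frac{1}{S}\sum_s
#'  \log p(y_k \mid f^{(s)}(x_k)) -
#'  \sum_{\ell, q} D_{KL}[q(v_{\ell q}) \| p(v_{\ell q})]}
#' where \eqn{f^{(s)}} are end-to-end pathwise samples through all layers,
#' optionally with the analytic gradient with respect to every trainable
#' parameter (variational means and covariance factors, mixing weights,
#' decays, lengthscales, noise variance). Missing targets (`NA`) are
#' excluded from the likelihood.
#'
#' @param model a `dlfm_vip` model.
#' @param x,y minibatch inputs and targets (model scale; `NA` = missing).
#' @param n_total total number of training observations.
#' @param n_samples number of end-to-end pathwise samples.
#' @param seed optional seed for the draws.
#' @param compute_grad also return the gradient structure.
#' @return list with `value`, `loglik`, `kl`, and optionally `grads`.
#' @export
elbo_vip <- function(model, x, y, n_total = nrow(as.matrix(x)),
                     n_samples = 1, seed = NULL, compute_grad = FALSE) {
  x <- as.matrix(x); y <- as.matrix(y)
  m_batch <- nrow(x)
  if (m_batch < 1) stop("empty minibatch")
  stopifnot(nrow(y) == m_batch, ncol(y) == model$d_out, n_samples >= 1)
  sigma2_y <- softplus(model$rho_sigma2_y)
  scale_n <- n_total / m_batch
  obs <- is.finite(y)

  reals <- lapply(model$layers, function(lay) {
    lapply(lay$forces, force_realise, jitter = model$jitter)
  })

  run <- function() {
    draws <- lapply(seq_len(n_samples), function(s) {
      if (!model$resample_basis) {
        dr <- model$fixed_basis
        for (l in seq_along(dr)) for (qi in seq_along(dr[[l]])) {
          dr[[l]][[qi]]$eta <- stats::rnorm(length(dr[[l]][[qi]]$eta))
        }
        dr
      } else vip_draw_eps(model)
    })
    loglik <- 0
    dsig2 <- 0
    grads <- if (compute_grad) params_zero(vip_params(model)) else NULL
    for (s in seq_len(n_samples)) {
      cur <- x
      fwds <- vector("list", model$n_layers)
      for (l in seq_len(model$n_layers)) {
        fwds[[l]] <- vip_layer_forward(model$layers[[l]], reals[[l]], cur,
                                       draws[[s]][[l]],
                                       keep_cache = compute_grad)
        cur <- fwds[[l]]$output
      }
      if (!all(is.finite(cur))) stop("non-finite pathwise sample")
      resid <- y - cur
      resid[!obs] <- 0
      ll_s <- sum(obs) * (-0.5 * log(2 * pi * sigma2_y)) -
        sum(resid^2) / (2 * sigma2_y)
      loglik <- loglik + ll_s / n_samples
      if (compute_grad) {
        dF <- (scale_n / n_samples) * resid / sigma2_y
        for (l in rev(seq_len(model$n_layers))) {
          bk <- vip_layer_backward(model$layers[[l]], fwds[[l]], dF)
          grads$layers[[l]] <- params_add(grads$layers[[l]], bk$grads)
          dF <- bk$dX
        }
        dsig2 <- dsig2 + (scale_n / n_samples) *
          (-0.5 * sum(obs) / sigma2_y + sum(resid^2) / (2 * sigma2_y^2))
      }
    }
    list(loglik = loglik, grads = grads, dsig2 = dsig2)
  }
  lik <- if (is.null(seed)) run() else with_seed(seed, run())

  kl <- vip_kl_terms(model, reals, compute_grad = compute_grad)
  value <- scale_n * lik$loglik - kl$value
  out <- list(value = value, loglik = scale_n * lik$loglik, kl = kl$value)
  if (compute_grad) {
    grads <- params_add(lik$grads, params_scale(kl$grads, -1))
    grads$rho_sigma2_y <- grads$rho_sigma2_y +
      lik$dsig2 * softplus_grad(model$rho_sigma2_y)
    out$grads <- grads
  }
  out
}

# KL penalty over all layers/forces plus gradients wrt mu, the covariance
# factor and (through K_uu) the lengthscale.
vip_kl_terms <- function(model, reals, compute_grad = TRUE) {
  total <- 0
  grads <- if (compute_grad) params_zero(vip_params(model)) else NULL
  for (l in seq_along(model$layers)) {
    lay <- model$layers[[l]]
    for (qi in seq_len(lay$Q)) {
      real <- reals[[l]][[qi]]
      M <- real$M
      if (M == 0) next
      L <- real$L
      Kinv <- chol2inv(real$cholK)
      Sigma <- tcrossprod(L)
      KinvL <- Kinv %*% L
      Kinvmu <- drop(Kinv %*% real$mu)
      total <- total + 0.5 * (sum(KinvL * L) + sum(real$mu * Kinvmu) - M +
                                2 * sum(log(diag(real$cholK))) -
                                2 * sum(log(diag(L))))
      if (compute_grad) {
        g <- grads$layers[[l]]$forces[[qi]]
        g$mu <- g$mu + Kinvmu
        dL <- KinvL
        diag(dL) <- diag(dL) - 1 / diag(L)
        g$rho_Ldiag <- g$rho_Ldiag + diag(dL) *
          softplus_grad(model$layers[[l]]$forces[[qi]]$rho_Ldiag)
        if (M > 1) g$L_off <- g$L_off + dL[lower.tri(dL)]
        KinvSKinv <- KinvL %*% t(KinvL)
        dK <- 0.5 * (Kinv - KinvSKinv - tcrossprod(Kinvmu))
        dK0dl <- real$K0 * (2 * real$d2 / real$ell^3)
        g$rho_ell <- g$rho_ell + sum(dK * dK0dl) *
          softplus_grad(model$layers[[l]]$forces[[qi]]$rho_ell)
        grads$layers[[l]]$forces[[qi]] <- g
      }
    }
  }
  list(value = total, grads = grads)
}

# Reverse pass through one layer for one pathwise sample. `fw` is the cached
# result of vip_layer_forward(..., keep_cache = TRUE); dF is the gradient of
# the objective wrt the layer output (N x D). Returns dX (N x P) and a
# gradient structure matching vip_params(model)$layers[[l]].
vip_layer_backward <- function(layer, fw, dF) {
  X <- fw$X
  N <- nrow(X); P <- layer$P; D <- layer$D; B <- layer$B
  gamma <- fw$gamma
  SB <- sqrt(2 / B)
  g <- list(forces = vector("list", layer$Q),
            a = matrix(0, D, layer$Q),
            rho_gamma = matrix(0, D, P))
  dgamma <- matrix(0, D, P)
  dX <- matrix(0, N, P)
  for (qi in seq_len(layer$Q)) {
    ca <- fw$caches[[qi]]
    real <- ca$real
    aq <- layer$a[, qi]
    # mixing weights and the bracket cotangent
    g$a[, qi] <- colSums(dF * ca$bracket)
    Wm <- sweep(dF, 2, aq, "*") # N x D, weight on bracket
    dell <- 0
    dtheta <- matrix(0, B, P)

    # ---- cosine (prior-path) part ----
    dCx <- SB * (Wm %*% Re(ca$u))   # N x B
    dSx <- -SB * (Wm %*% Im(ca$u))
    dArg <- -dCx * ca$Sx + dSx * ca$Cx
    dX <- dX + dArg %*% ca$theta
    dtheta <- dtheta + crossprod(dArg, X)
    # complex cotangent of u: L = sum Re(G * du) under perturbations
    G <- SB * (t(Wm) %*% (ca$Cx + (0+1i) * ca$Sx)) # D x B complex
    H <- -G * ca$u # shared factor; du/dpar = -u / (gamma_dp + i theta_ip)
    for (p in seq_len(P)) {
      denfac <- outer(gamma[, p], ca$theta[, p],
                      function(gm, th) complex(real = gm, imaginary = th))
      Hp <- H / denfac
      dgamma[, p] <- dgamma[, p] + rowSums(Re(Hp))
      dtheta[, p] <- dtheta[, p] - colSums(Im(Hp))
    }

    # ---- canonical (update) part ----
    M <- real$M
    dmu <- NULL; dLmat <- NULL
    if (M > 0) {
      dalpha <- numeric(M)
      for (d in seq_len(D)) {
        Td_w <- outer(Wm[, d], ca$alpha) # N x M cotangent of T_d
        dalpha <- dalpha + drop(crossprod(ca$Ig[[d]]$T, Wm[, d]))
        for (p in seq_len(P)) {
          other <- Td_w
          for (p2 in seq_len(P)) {
            if (p2 != p) other <- other * ca$Ig[[d]][[p2]]$value
          }
          Igp <- ca$Ig[[d]][[p]]
          dgamma[d, p] <- dgamma[d, p] + sum(other * Igp$dgamma)
          dell <- dell + sum(other * Igp$dell)
          dX[, p] <- dX[, p] + rowSums(other * Igp$dx)
        }
      }
      # alpha = K^{-1}(v - phi_z w) chain
      Ks <- drop(chol_solve(real$cholK, dalpha))
      dmu <- Ks
      dLmat <- outer(Ks, ca$dr$eta)
      dphi_z <- -outer(Ks, ca$dr$w) # M x B
      dArgZ <- -dphi_z * SB * sin(ca$argZ)
      dtheta <- dtheta + crossprod(dArgZ, real$z)
      dKlik <- -outer(Ks, ca$alpha)
      dK0dl <- real$K0 * (2 * real$d2 / real$ell^3)
      dell <- dell + sum(dKlik * dK0dl)
    }

    # theta = eps * sqrt(2)/ell  =>  dtheta/dell = -theta/ell
    dell <- dell - sum(dtheta * ca$theta) / real$ell

    fo <- layer$forces[[qi]]
    gf <- list(mu = numeric(length(fo$mu)),
               rho_Ldiag = numeric(length(fo$rho_Ldiag)),
               L_off = numeric(length(fo$L_off)),
               rho_ell = 0)
    if (M > 0) {
      gf$mu <- dmu
      gf$rho_Ldiag <- diag(dLmat) * softplus_grad(fo$rho_Ldiag)
      if (M > 1) gf$L_off <- dLmat[lower.tri(dLmat)]
    }
    gf$rho_ell <- dell * softplus_grad(fo$rho_ell)
    g$forces[[qi]] <- gf
  }
  g$rho_gamma <- dgamma * softplus_grad(layer$rho_gamma)
  list(dX = dX, grads = g)
}
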