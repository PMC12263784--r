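# Evidence lower bound of the weight-space model and its analytic gradient.
# The bound is
#   (N/M) * sum_batch (1/N_MC) * sum_r log p(y | x, Psi_r, Theta) - KL(q||p)
# with Psi the weights and spectral frequencies of all layers. Gradients are
# computed by a hand-written reverse pass through the feature maps.

# KL of the whole model plus gradients wrt all parameters that enter it.
rff_kl_terms <- function(model, compute_grad = TRUE) {
  total <- 0
  grads <- if (compute_grad) rff_params(model) else NULL
  if (compute_grad) grads <- params_zero(grads)
  for (l in seq_along(model$layers)) {
    for (b in seq_along(model$layers[[l]]$blocks)) {
      block <- model$layers[[l]]$blocks[[b]]
      p <- block$params
      s_w <- softplus(p$rho_s_w)
      # weights: prior N(0, 1)
      total <- total + kl_gaussian(p$m_w, s_w^2, 0, 1)
      # frequencies: prior N(0, 2/ell^2), per-force column groups
      s_o <- softplus(p$rho_s_omega)
      ell <- softplus(p$rho_ell)
      if (block$type == "lfm") {
        vp_cols <- rep(2 / ell^2, each = block$n_rf)
      } else {
        vp_cols <- rep(2 / ell^2, block$n_rf)
      }
      vp <- matrix(vp_cols, nrow(p$m_omega), ncol(p$m_omega), byrow = TRUE)
      total <- total + kl_gaussian(p$m_omega, s_o^2, 0, vp)
      if (compute_grad) {
        g <- grads$layers[[l]][[b]]
        g$m_w <- g$m_w + p$m_w
        g$rho_s_w <- g$rho_s_w + (s_w - 1 / s_w) * softplus_grad(p$rho_s_w)
        g$m_omega <- g$m_omega + p$m_omega / vp
        g$rho_s_omega <- g$rho_s_omega +
          (s_o / vp - 1 / s_o) * softplus_grad(p$rho_s_omega)
        # d KL / d vp, then vp = 2/ell^2
        dvp <- 0.5 * (1 / vp - (s_o^2 + p$m_omega^2) / vp^2)
        if (block$type == "lfm") {
          grp <- rep(seq_len(block$q), each = block$n_rf)
          dvp_per_ell <- as.numeric(
            tapply(colSums(dvp), grp, sum))
        } else {
          dvp_per_ell <- sum(dvp)
        }
        g$rho_ell <- g$rho_ell +
          dvp_per_ell * (-4 / ell^3) * softplus_grad(p$rho_ell)
        grads$layers[[l]][[b]] <- g
      }
    }
  }
  list(value = total, grads = grads)
}

#' Stochastic variational bound of the weight-space model
#'
#' Evaluates the minibatch evidence lower bound
#' \deqn{\frac{N}{M}\sum_{k \in batch}\frac{1}{N_{MC}}\sum_r
#'       \log p(y_k \mid x_k, \tilde\Psi_r) - D_{KL}[q(\Psi)\|p(\Psi)]}
#' under a Gaussian likelihood, optionally with its analytic gradient with
#' respect to every trainable parameter. Missing targets (`NA`) contribute
#' neither to the likelihood nor to its gradient.
#'
#' @param model a `dlfm_rff` model.
#' @param x,y minibatch inputs (`m` x `d_in`) and targets (`m` x `d_out`,
#'   `NA` = missing). Assumed to be on the model's internal scale; [fit()]
#'   handles scaling.
#' @param n_total total number of training observations `N` (the `N/M`
#'   factor scales the likelihood term only).
#' @param n_mc number of Monte Carlo draws of the weights.
#' @param seed optional seed for the draws.
#' @param local use the local reparameterization trick (sample layer
#'   pre-activations rather than weights).
#' @param compute_grad also return the gradient structure.
#' @return list with `value`, `loglik`, `kl`, and (optionally) `grads`.
#' @export
elbo_rff <- function(model, x, y, n_total = nrow(as.matrix(x)), n_mc = 1,
                     seed = NULL, local = FALSE, compute_grad = FALSE) {
  x <- as.matrix(x); y <- as.matrix(y)
  m_batch <- nrow(x)
  if (m_batch < 1) stop("empty minibatch")
  if (n_mc < 1) stop("n_mc must be >= 1")
  stopifnot(nrow(y) == m_batch, ncol(y) == model$d_out)
  sigma2_y <- softplus(model$rho_sigma2_y)
  scale_n <- n_total / m_batch
  obs <- is.finite(y)

  run <- function() {
    loglik <- 0
    grads <- NULL
    dsig2 <- 0
    if (compute_grad) grads <- params_zero(rff_params(model))
    for (r in seq_len(n_mc)) {
      if (local) {
        fw <- rff_forward(model, x, local = TRUE, keep_cache = compute_grad)
      } else {
        draws <- sample_variational(model, sample_w = TRUE)
        fw <- rff_forward(model, x, draws = draws, keep_cache = compute_grad)
      }
      resid <- y - fw$output
      resid[!obs] <- 0
      ll_r <- sum(obs) * (-0.5 * log(2 * pi * sigma2_y)) -
        sum(resid^2) / (2 * sigma2_y)
      loglik <- loglik + ll_r / n_mc
      if (compute_grad) {
        dF <- (scale_n / n_mc) * resid / sigma2_y
        g_r <- rff_backward(model, fw$caches, dF)
        grads <- params_add(grads, g_r)
        dsig2 <- dsig2 + (scale_n / n_mc) *
          (-0.5 * sum(obs) / sigma2_y + sum(resid^2) / (2 * sigma2_y^2))
      }
    }
    list(loglik = loglik, grads = grads, dsig2 = dsig2)
  }
  lik <- if (is.null(seed)) run() else with_seed(seed, run())

  kl <- rff_kl_terms(model, compute_grad = compute_grad)
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

# Reverse pass through all layers. dF_out is the gradient of the objective
# wrt the model output (already scaled). Returns a gradient structure in the
# shape of rff_params(model) (likelihood part only; KL handled separately).
rff_backward <- function(model, caches, dF_out) {
  grads <- params_zero(rff_params(model))
  dF <- dF_out
  for (l in rev(seq_len(model$n_layers))) {
    blocks <- model$layers[[l]]$blocks
    col0 <- 0L
    dX_total <- NULL
    for (b in seq_along(blocks)) {
      block <- blocks[[b]]
      cache <- caches[[l]][[b]]
      dFb <- dF[, col0 + seq_len(block$d_out), drop = FALSE]
      col0 <- col0 + block$d_out
      p <- block$params
      g <- grads$layers[[l]][[b]]
      if (cache$local) {
        s_w2 <- cache$real$s_w^2
        V <- pmax(cache$V, 1e-300)
        dm_w <- crossprod(cache$phi, dFb)
        dVmat <- dFb * cache$xi * 0.5 / sqrt(V)
        ds2_w <- crossprod(cache$phi^2, dVmat)
        dphi <- tcrossprod(dFb, p$m_w) +
          2 * cache$phi * tcrossprod(dVmat, s_w2)
        g$m_w <- g$m_w + dm_w
        g$rho_s_w <- g$rho_s_w +
          ds2_w * 2 * cache$real$s_w * softplus_grad(p$rho_s_w)
      } else {
        dW <- crossprod(cache$phi, dFb)
        eps_w <- (cache$W - p$m_w) / cache$real$s_w
        g$m_w <- g$m_w + dW
        g$rho_s_w <- g$rho_s_w + dW * eps_w * softplus_grad(p$rho_s_w)
        dphi <- tcrossprod(dFb, cache$W)
      }
      fb <- feature_backward(cache$fcache, dphi)
      g$m_omega <- g$m_omega + fb$dOmega
      g$rho_s_omega <- g$rho_s_omega +
        fb$dOmega * block$eps_omega * softplus_grad(p$rho_s_omega)
      if (block$type == "lfm") {
        g$c <- g$c + colSums(dFb)
        g$rho_gamma <- g$rho_gamma +
          fb$dgamma * softplus_grad(p$rho_gamma)
        g$sens <- g$sens + fb$dsens
      } else {
        g$rho_sigma2 <- g$rho_sigma2 +
          fb$dsigma2 * softplus_grad(p$rho_sigma2)
      }
      grads$layers[[l]][[b]] <- g
      dX_total <- if (is.null(dX_total)) fb$dX else dX_total + fb$dX
    }
    dF <- dX_total
  }
  grads
}
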