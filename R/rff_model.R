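#' Deep latent force model with random Fourier response features
#'
#' Builds the weight-space formulation of the deep latent force model: a
#' stack of layers, each mapping its input through realified first-order-ODE
#' response features \eqn{\Phi_{LFM}(F, \gamma, \Omega)} followed by a linear
#' weight matrix and a learnable initial-condition bias,
#' \eqn{F^{(\ell+1)} = \Phi^{(\ell)}_{LFM} W^{(\ell)} + c^{(\ell)}}.
#' Variational Gaussians are placed over all spectral frequencies and
#' weights; the frequency draws follow the VAR-FIXED strategy (standard
#' normal draws fixed at construction, only means and variances learned).
#' At the final layer each output receives its own decay, frequency and
#' weight block. With `feature_type = "eq"` the layers use plain EQ
#' random Fourier features instead, giving the non-physics-informed deep GP
#' baseline with an identical inference scheme.
#'
#' @param d_in,d_out input and output dimension of the data.
#' @param n_layers total number of layers (hidden layers plus the output
#'   layer).
#' @param hidden_width width of the hidden layers (defaults to `d_out`,
#'   mirroring the multi-output experiments).
#' @param n_rf number of random features per latent force.
#' @param q number of latent forces per layer.
#' @param feature_type `"lfm"` for ODE response features (the deep latent
#'   force model), `"eq"` for plain EQ features (deep GP baseline).
#' @param per_output_final give each output its own parameter block at the
#'   final layer (`"lfm"` only; ignored otherwise).
#' @param gamma,lengthscale,sigma2,sigma2_y initial values of the decay,
#'   latent lengthscale, EQ marginal variance (baseline only) and likelihood
#'   noise variance.
#' @param seed integer seed controlling the fixed standard-normal frequency
#'   draws and the weight-mean initialisation.
#' @return an object of class `dlfm_rff` (also `dlfm_model`).
#' @export
dlfm_rff <- function(d_in, d_out, n_layers = 2, hidden_width = d_out,
                     n_rf = 100, q = 1,
                     feature_type = c("lfm", "eq"),
                     per_output_final = NULL,
                     gamma = 1, lengthscale = 1, sigma2 = 1, sigma2_y = 0.1,
                     seed = 1) {
  feature_type <- match.arg(feature_type)
  stopifnot(d_in >= 1, d_out >= 1, n_layers >= 1, n_rf >= 1, q >= 1,
            sigma2_y > 0)
  if (is.null(per_output_final)) {
    per_output_final <- feature_type == "lfm" && d_out > 1
  }
  widths <- c(d_in, rep(hidden_width, n_layers - 1), d_out)
  layers <- vector("list", n_layers)
  for (l in seq_len(n_layers)) {
    final <- l == n_layers
    n_blocks <- if (final && per_output_final) d_out else 1L
    block_out <- if (final && per_output_final) 1L else widths[l + 1]
    blocks <- vector("list", n_blocks)
    for (b in seq_len(n_blocks)) {
      blocks[[b]] <- new_rff_block(
        d_in = widths[l], d_out = block_out, n_rf = n_rf, q = q,
        type = feature_type, gamma = gamma, lengthscale = lengthscale,
        sigma2 = sigma2, seed = derive_seed(seed, l * 131 + b))
    }
    layers[[l]] <- list(blocks = blocks)
  }
  model <- list(layers = layers,
                n_layers = n_layers,
                d_in = d_in, d_out = d_out,
                feature_type = feature_type,
                per_output_final = per_output_final,
                rho_sigma2_y = softplus_inv(sigma2_y),
                scaling = identity_scaling(d_in, d_out),
                seed = seed)
  class(model) <- c("dlfm_rff", "dlfm_model")
  model
}

new_rff_block <- function(d_in, d_out, n_rf, q, type, gamma, lengthscale,
                          sigma2, seed) {
  J <- if (type == "lfm") q * n_rf else n_rf
  with_seed(seed, {
    eps_omega <- matrix(stats::rnorm(d_in * J), d_in, J)
    m_w <- matrix(stats::rnorm(2 * J * d_out, sd = 0.3), 2 * J, d_out)
  })
  params <- list(
    m_omega = matrix(0, d_in, J),
    rho_s_omega = matrix(softplus_inv(sqrt(2) / lengthscale), d_in, J),
    m_w = m_w,
    rho_s_w = matrix(softplus_inv(0.1), 2 * J, d_out))
  if (type == "lfm") {
    params$c <- numeric(d_out)
    params$rho_gamma <- rep(softplus_inv(gamma), d_in)
    params$rho_ell <- rep(softplus_inv(lengthscale), q)
    params$sens <- rep(1, q)
  } else {
    params$rho_ell <- softplus_inv(lengthscale)
    params$rho_sigma2 <- softplus_inv(sigma2)
  }
  list(type = type, d_in = d_in, d_out = d_out, n_rf = n_rf, q = q, J = J,
       eps_omega = eps_omega, params = params)
}

# Realised (constrained) quantities of a block given its current parameters.
block_realise <- function(block) {
  p <- block$params
  s_omega <- softplus(p$rho_s_omega)
  Omega <- p$m_omega + s_omega * block$eps_omega
  out <- list(Omega = Omega, s_omega = s_omega,
              s_w = softplus(p$rho_s_w))
  if (block$type == "lfm") {
    out$gamma <- softplus(p$rho_gamma)
    out$ell <- softplus(p$rho_ell)
    out$sens <- p$sens
    out$c <- p$c
  } else {
    out$ell <- softplus(p$rho_ell)
    out$sigma2 <- softplus(p$rho_sigma2)
    out$c <- numeric(block$d_out)
  }
  out
}

feature_block_spec <- function(block, real) {
  if (block$type == "lfm") {
    list(type = "lfm", gamma = real$gamma, Omega = real$Omega,
         sens = real$sens, n_rf = block$n_rf, q = block$q)
  } else {
    list(type = "eq", Omega = real$Omega, sigma2 = real$sigma2,
         n_rf = block$n_rf, q = 1L)
  }
}

#' Draw from the variational distribution of a weight-space model
#'
#' Realises the spectral frequencies and weights used by a forward pass.
#' Frequencies follow the VAR-FIXED contract: \eqn{\Omega = m + s\,\epsilon}
#' with the standard-normal draws \eqn{\epsilon} fixed at construction, so
#' they are a deterministic function of the variational parameters. Weights
#' are sampled as \eqn{W = m_W + s_W \epsilon_W} with fresh draws when
#' `sample_w = TRUE`, and set to their variational means otherwise (the
#' deterministic test-time mode).
#'
#' @param model a `dlfm_rff` model.
#' @param sample_w logical; sample the weights or use their means.
#' @param seed optional integer seed for the weight draws.
#' @return list with one element per layer, each a list of per-block
#'   `list(Omega, W)`.
#' @export
sample_variational <- function(model, sample_w = TRUE, seed = NULL) {
  stopifnot(inherits(model, "dlfm_rff"))
  draw_all <- function() {
    lapply(model$layers, function(layer) {
      lapply(layer$blocks, function(block) {
        real <- block_realise(block)
        W <- if (sample_w) {
          eps <- matrix(stats::rnorm(length(block$params$m_w)),
                        nrow(block$params$m_w), ncol(block$params$m_w))
          block$params$m_w + real$s_w * eps
        } else {
          block$params$m_w
        }
        list(Omega = real$Omega, W = W)
      })
    })
  }
  if (is.null(seed)) draw_all() else with_seed(seed, draw_all())
}

#' Forward pass of one weight-space layer
#'
#' Computes \eqn{\Phi(F_{in}) W + c} for a single parameter block with
#' explicitly supplied frequency and weight matrices. Exposed for
#' inspection and testing; training and prediction use the same code path
#' internally.
#'
#' @param f_in numeric input matrix `n` x `d_in`.
#' @param block a block of a `dlfm_rff` model (see `model$layers`).
#' @param omega realised spectral frequency matrix.
#' @param w realised weight matrix.
#' @param layer_index integer used in overflow diagnostics.
#' @return numeric matrix `n` x `d_out`.
#' @export
layer_forward <- function(f_in, block, omega, w, layer_index = NA) {
  real <- block_realise(block)
  spec <- feature_block_spec(block, real)
  spec$Omega <- omega
  ff <- feature_forward(as.matrix(f_in), spec)
  if (!all(is.finite(ff$phi))) {
    stop("non-finite features in layer ", layer_index,
         " (overflow of exp(-gamma * F); inputs too negative for the decay)")
  }
  out <- ff$phi %*% w
  sweep(out, 2, real$c, "+")
}

# Full forward pass. `draws` comes from sample_variational() (mode "sample"
# or "mean"), or is NULL with local = TRUE for local-reparameterization
# pre-activation sampling (training). Returns output and per-layer caches.
rff_forward <- function(model, X, draws = NULL, local = FALSE,
                        keep_cache = FALSE) {
  Fcur <- as.matrix(X)
  caches <- if (keep_cache) vector("list", model$n_layers) else NULL
  for (l in seq_len(model$n_layers)) {
    blocks <- model$layers[[l]]$blocks
    outs <- vector("list", length(blocks))
    bl_caches <- if (keep_cache) vector("list", length(blocks)) else NULL
    for (b in seq_along(blocks)) {
      block <- blocks[[b]]
      real <- block_realise(block)
      spec <- feature_block_spec(block, real)
      ff <- feature_forward(Fcur, spec)
      if (!all(is.finite(ff$phi))) {
        stop("non-finite features in layer ", l,
             " (overflow of exp(-gamma * F))")
      }
      if (local) {
        A <- ff$phi %*% block$params$m_w
        V <- (ff$phi^2) %*% (real$s_w^2)
        xi <- matrix(stats::rnorm(length(A)), nrow(A), ncol(A))
        out <- A + sqrt(V) * xi
        out <- sweep(out, 2, real$c, "+")
        if (keep_cache) {
          bl_caches[[b]] <- list(real = real, fcache = ff$cache, local = TRUE,
                                 V = V, xi = xi, phi = ff$phi)
        }
      } else {
        W <- draws[[l]][[b]]$W
        out <- sweep(ff$phi %*% W, 2, real$c, "+")
        if (keep_cache) {
          bl_caches[[b]] <- list(real = real, fcache = ff$cache, local = FALSE,
                                 W = W, phi = ff$phi)
        }
      }
      outs[[b]] <- out
    }
    if (keep_cache) caches[[l]] <- bl_caches
    Fcur <- do.call(cbind, outs)
  }
  list(output = Fcur, caches = caches)
}

#' Per-output final layer of a weight-space model
#'
#' Applies the final layer of a model built with `per_output_final = TRUE`:
#' output column `d` is produced by its own decay, frequency and weight
#' block, so outputs with different dynamics get different filters.
#'
#' @param f_in numeric input matrix.
#' @param blocks list of per-output blocks (e.g.
#'   `model$layers[[model$n_layers]]$blocks`).
#' @param draws list of per-block `list(Omega, W)` realisations.
#' @return numeric matrix with one column per block.
#' @export
final_layer_per_output <- function(f_in, blocks, draws) {
  stopifnot(length(blocks) == length(draws))
  cols <- lapply(seq_along(blocks), function(b) {
    layer_forward(f_in, blocks[[b]], draws[[b]]$Omega, draws[[b]]$W,
                  layer_index = "final")
  })
  do.call(cbind, cols)
}

# ---- trainable parameter plumbing ------------------------------------------

rff_params <- function(model) {
  list(layers = lapply(model$layers, function(layer) {
    lapply(layer$blocks, function(block) block$params)
  }),
  rho_sigma2_y = model$rho_sigma2_y)
}

rff_set_params <- function(model, params) {
  for (l in seq_along(model$layers)) {
    for (b in seq_along(model$layers[[l]]$blocks)) {
      model$layers[[l]]$blocks[[b]]$params <- params$layers[[l]][[b]]
    }
  }
  model$rho_sigma2_y <- params$rho_sigma2_y
  model
}
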