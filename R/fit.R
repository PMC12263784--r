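#' Fit a deep latent force model
#'
#' Maximises the stochastic variational bound of a model with AdamW on the
#' flattened unconstrained parameters. Inputs are min-max scaled to
#' \eqn{[0,1]} and targets standardised internally (per output, on the
#' training data); predictions are returned on the original scale.
#'
#' @param model a `dlfm_rff` or `dlfm_vip` model.
#' @param x numeric input matrix (`n` x `d_in`) or vector.
#' @param y numeric target matrix (`n` x `d_out`); `NA` marks missing
#'   values, which are excluded from the likelihood.
#' @param ... passed to methods.
#' @return the fitted model, with a `fit_report` element holding the bound
#'   trace, iteration count and seeds.
#' @export
fit <- function(model, x, y, ...) UseMethod("fit")

#' @rdname fit
#' @param iterations number of optimisation steps.
#' @param lr AdamW learning rate.
#' @param batch_size minibatch size (capped at `n`).
#' @param n_mc Monte Carlo draws per step.
#' @param local use local-reparameterization sampling during training.
#' @param weight_decay decoupled weight decay.
#' @param seed integer seed making the whole run reproducible.
#' @param scale fit internal input/target scaling (disable when the data
#'   are already on the model scale).
#' @param x_scale `"unit"` min-max scales inputs to \eqn{[0,1]};
#'   `"none"` keeps the native input units (targets are standardised either
#'   way). Decay and frequency parameters live on the scaled axis, so for
#'   dynamical data whose frequencies are order one in native units,
#'   `"none"` keeps the first-order filter response well conditioned.
#' @param record_every record the bound every this many iterations.
#' @param verbose print the bound while training.
#' @export
fit.dlfm_rff <- function(model, x, y, iterations = 2000, lr = 0.01,
                         batch_size = 128, n_mc = 1, local = TRUE,
                         weight_decay = 0, seed = 1, scale = TRUE,
                         x_scale = c("unit", "none"),
                         record_every = 50, verbose = FALSE, ...) {
  fit_dlfm(model, x, y, iterations, lr, batch_size, weight_decay, seed,
           scale, match.arg(x_scale), record_every, verbose,
           function(mod, xb, yb, n) {
             elbo_rff(mod, xb, yb, n_total = n, n_mc = n_mc, local = local,
                      compute_grad = TRUE)
           },
           rff_params, rff_set_params)
}

#' @rdname fit
#' @param n_samples pathwise samples per step.
#' @export
fit.dlfm_vip <- function(model, x, y, iterations = 2000, lr = 0.01,
                         batch_size = 128, n_samples = 1,
                         weight_decay = 0, seed = 1, scale = TRUE,
                         x_scale = c("unit", "none"),
                         record_every = 50, verbose = FALSE, ...) {
  fit_dlfm(model, x, y, iterations, lr, batch_size, weight_decay, seed,
           scale, match.arg(x_scale), record_every, verbose,
           function(mod, xb, yb, n) {
             elbo_vip(mod, xb, yb, n_total = n, n_samples = n_samples,
                      compute_grad = TRUE)
           },
           vip_params, vip_set_params)
}

# Shared AdamW loop. objective(mod, xb, yb, n_total) must return
# list(value, grads) of the bound to MAXIMISE.
fit_dlfm <- function(model, x, y, iterations, lr, batch_size, weight_decay,
                     seed, scale, x_scale, record_every, verbose,
                     objective, get_params, set_params) {
  x <- as.matrix(x); y <- as.matrix(y)
  stopifnot(nrow(x) == nrow(y), ncol(x) == model$d_in,
            ncol(y) == model$d_out, iterations >= 1)
  if (scale) {
    model$scaling <- fit_scaling(x, y)
    if (x_scale == "none") {
      model$scaling$x_min <- rep(0, model$d_in)
      model$scaling$x_range <- rep(1, model$d_in)
    }
  }
  xs <- scale_x(model$scaling, x)
  ys <- scale_y(model$scaling, y)
  n <- nrow(xs)
  bs <- min(batch_size, n)
  template <- get_params(model)
  theta <- flatten_params(template)
  state <- adamw_init(length(theta))
  trace_it <- integer(0)
  trace_elbo <- numeric(0)
  with_seed(seed, {
    for (it in seq_len(iterations)) {
      idx <- if (bs < n) sample.int(n, bs) else seq_len(n)
      model <- set_params(model, unflatten_params(theta, template))
      ob <- objective(model, xs[idx, , drop = FALSE],
                      ys[idx, , drop = FALSE], n)
      if (!is.finite(ob$value)) {
        stop("bound diverged (non-finite) at iteration ", it,
             "; lower the learning rate")
      }
      g <- flatten_params(ob$grads)
      st <- adamw_step(theta, -g, state, lr = lr,
                       weight_decay = weight_decay)
      theta <- st$theta; state <- st$state
      if (it == 1L || it %% record_every == 0L || it == iterations) {
        trace_it <- c(trace_it, it)
        trace_elbo <- c(trace_elbo, ob$value)
        if (verbose) cat(sprintf("iter %6d  bound %.4f\n", it, ob$value))
      }
    }
  })
  model <- set_params(model, unflatten_params(theta, template))
  model$fit_report <- list(
    iterations = iterations, lr = lr, batch_size = bs, seed = seed,
    n_obs = n,
    trace = data.frame(iteration = trace_it, elbo = trace_elbo))
  model
}
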