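#' Normalised mean squared error
#'
#' Mean squared error divided by the (population) variance of the observed
#' targets, so predicting the target mean scores 1. Computed over non-`NA`
#' targets, pooled across outputs.
#'
#' @param y_true,y_pred numeric matrices or vectors of equal shape.
#' @return nonnegative scalar.
#' @examples
#' nmse(c(0, 2), c(1, 1)) # 1
#' @export
nmse <- function(y_true, y_pred) {
  y_true <- as.matrix(y_true); y_pred <- as.matrix(y_pred)
  obs <- is.finite(y_true)
  if (!any(obs)) stop("no observed targets")
  yt <- y_true[obs]; yp <- y_pred[obs]
  mean((yt - yp)^2) / mean((yt - mean(yt))^2)
}

#' Root mean squared error
#'
#' @inheritParams nmse
#' @return nonnegative scalar over non-`NA` targets.
#' @export
rmse <- function(y_true, y_pred) {
  y_true <- as.matrix(y_true); y_pred <- as.matrix(y_pred)
  obs <- is.finite(y_true)
  sqrt(mean((y_true[obs] - y_pred[obs])^2))
}

#' Mean negative log likelihood of Gaussian predictions
#'
#' Average of \eqn{\frac{1}{2}\log(2\pi v) + (y - m)^2 / (2v)} over observed
#' targets, using a moment-matched Gaussian predictive (mean and total
#' variance per point).
#'
#' @param y_true observed targets (`NA` ignored).
#' @param mean,var predictive means and total variances (function-sample
#'   variance plus observation noise), same shape as `y_true`.
#' @return scalar; lower is better.
#' @export
mnll <- function(y_true, mean, var) {
  y_true <- as.matrix(y_true)
  mean <- as.matrix(mean); var <- as.matrix(var)
  if (any(var <= 0)) stop("predictive variances must be positive")
  obs <- is.finite(y_true)
  if (!any(obs)) stop("no observed targets")
  base::mean(0.5 * log(2 * pi * var[obs]) +
               (y_true[obs] - mean[obs])^2 / (2 * var[obs]))
}

# ---- predictive summaries --------------------------------------------------

# Moment-matched predictive summary from function samples (original scale).
# samples: S x N x D array of noiseless function samples; sigma2_y_orig:
# per-output observation-noise variance on the original scale.
new_predictive_summary <- function(samples, sigma2_y_orig) {
  S <- dim(samples)[1]; N <- dim(samples)[2]; D <- dim(samples)[3]
  mean_f <- apply(samples, c(2, 3), mean)
  var_f <- if (S > 1) apply(samples, c(2, 3), stats::var) else
    matrix(0, N, D)
  var_tot <- sweep(var_f, 2, sigma2_y_orig, "+")
  sd_tot <- sqrt(var_tot)
  structure(list(mean = mean_f, var_f = var_f, var = var_tot, sd = sd_tot,
                 lower = mean_f - 2 * sd_tot, upper = mean_f + 2 * sd_tot,
                 samples = samples, sigma2_y = sigma2_y_orig,
                 n_samples = S),
            class = "predictive_summary")
}

#' @export
print.predictive_summary <- function(x, ...) {
  cat("Predictive summary:", dim(x$mean)[1], "points,",
      dim(x$mean)[2], "outputs,", x$n_samples, "samples\n")
  cat("mean range:", paste(signif(range(x$mean), 4), collapse = " .. "),
      "\n")
  cat("avg predictive sd:", signif(mean(x$sd), 4), "\n")
  invisible(x)
}

#' Predict from a fitted weight-space model
#'
#' Draws posterior function samples (frequencies fixed by the VAR-FIXED
#' contract, weights sampled from their variational Gaussians) and returns a
#' moment-matched predictive summary on the original data scale. With
#' `sample = FALSE` the weights are set to their variational means, giving a
#' single fully deterministic prediction (identical across calls).
#'
#' @param object a fitted `dlfm_rff` model.
#' @param x new inputs (original scale).
#' @param n_samples posterior samples (forced to 1 when `sample = FALSE`).
#' @param sample sample the weights (`TRUE`) or use their means.
#' @param seed integer seed.
#' @param ... unused.
#' @return a `predictive_summary` with `mean`, `sd`, `lower`/`upper`
#'   (mean +/- 2 sd) and the raw `samples`.
#' @export
predict.dlfm_rff <- function(object, x, n_samples = 100, sample = TRUE,
                             seed = NULL, ...) {
  x <- as.matrix(x)
  xs <- scale_x(object$scaling, x)
  if (!sample) n_samples <- 1L
  run <- function() {
    sams <- array(0, dim = c(n_samples, nrow(xs), object$d_out))
    for (s in seq_len(n_samples)) {
      draws <- sample_variational(object, sample_w = sample)
      out <- rff_forward(object, xs, draws = draws)$output
      sams[s, , ] <- unscale_y(object$scaling, out)
    }
    sams
  }
  samples <- if (is.null(seed)) run() else with_seed(seed, run())
  sig2 <- softplus(object$rho_sigma2_y) * object$scaling$y_sd^2
  new_predictive_summary(samples, sig2)
}

#' Predict from a fitted inducing-point model
#'
#' Propagates pathwise posterior samples through the layer stack and
#' summarises them on the original data scale.
#'
#' @param object a fitted `dlfm_vip` model.
#' @param x new inputs (original scale).
#' @param n_samples number of end-to-end pathwise samples.
#' @param seed integer seed.
#' @param ... unused.
#' @return a `predictive_summary`.
#' @export
predict.dlfm_vip <- function(object, x, n_samples = 100, seed = NULL, ...) {
  x <- as.matrix(x)
  xs <- scale_x(object$scaling, x)
  co <- vip_compose(object, xs, n_samples = n_samples, seed = seed)
  raw <- co[[object$n_layers]]
  samples <- array(0, dim = dim(raw))
  for (s in seq_len(dim(raw)[1])) {
    samples[s, , ] <- unscale_y(object$scaling,
                                matrix(raw[s, , ], dim(raw)[2], dim(raw)[3]))
  }
  sig2 <- softplus(object$rho_sigma2_y) * object$scaling$y_sd^2
  new_predictive_summary(samples, sig2)
}

#' Evaluate predictions against held-out targets
#'
#' Convenience wrapper computing the three study metrics from a predictive
#' summary: normalised MSE, RMSE and moment-matched mean negative log
#' likelihood.
#'
#' @param summary a `predictive_summary`.
#' @param y_true held-out targets (`NA` ignored).
#' @return named list with `nmse`, `rmse`, `mnll`.
#' @export
evaluate_predictions <- function(summary, y_true) {
  stopifnot(inherits(summary, "predictive_summary"))
  list(nmse = nmse(y_true, summary$mean),
       rmse = rmse(y_true, summary$mean),
       mnll = mnll(y_true, summary$mean, summary$var))
}
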