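# Input/target scaling recorded on the model so that predictions and metrics
# are reported on the original data scale. Inputs are min-max scaled to
# [0, 1]; targets are standardised per output on the training split.

identity_scaling <- function(d_in, d_out) {
  list(x_min = rep(0, d_in), x_range = rep(1, d_in),
       y_mean = rep(0, d_out), y_sd = rep(1, d_out))
}

fit_scaling <- function(x, y) {
  x <- as.matrix(x); y <- as.matrix(y)
  x_min <- apply(x, 2, min)
  x_range <- apply(x, 2, max) - x_min
  x_range[x_range == 0] <- 1
  y_mean <- apply(y, 2, mean, na.rm = TRUE)
  y_sd <- apply(y, 2, stats::sd, na.rm = TRUE)
  y_sd[!is.finite(y_sd) | y_sd == 0] <- 1
  list(x_min = x_min, x_range = x_range, y_mean = y_mean, y_sd = y_sd)
}

scale_x <- function(scaling, x) {
  x <- as.matrix(x)
  sweep(sweep(x, 2, scaling$x_min, "-"), 2, scaling$x_range, "/")
}

scale_y <- function(scaling, y) {
  y <- as.matrix(y)
  sweep(sweep(y, 2, scaling$y_mean, "-"), 2, scaling$y_sd, "/")
}

unscale_y <- function(scaling, y) {
  y <- as.matrix(y)
  sweep(sweep(y, 2, scaling$y_sd, "*"), 2, scaling$y_mean, "+")
}
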