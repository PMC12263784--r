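#' Smooth positivity transform
#'
#' `softplus()` maps unconstrained reals to positive reals via
#' \eqn{\log(1 + e^x)}; `softplus_inv()` is its inverse. All positive
#' parameters in the package (decays, lengthscales, variances, variational
#' standard deviations) are stored unconstrained and pushed through this
#' bijection, so gradient-based optimisation never leaves the feasible set.
#'
#' @param x numeric vector.
#' @return numeric vector of the same shape.
#' @export
softplus <- function(x) {
  # log1p(exp(x)) overflows for large x; identity is exact there
  out <- ifelse(x > 30, x, log1p(exp(pmin(x, 30))))
  out
}

#' @rdname softplus
#' @export
softplus_inv <- function(x) {
  stopifnot(all(x > 0))
  ifelse(x > 30, x, log(expm1(x)))
}

# d softplus(x) / dx
softplus_grad <- function(x) {
  1 / (1 + exp(-x))
}

#' Scaled complementary error function
#'
#' Computes \eqn{e^{x^2}\,\mathrm{erfc}(x)} without overflow. For
#' \eqn{x \le 25} the direct product is representable; above that an
#' asymptotic expansion is used (relative error < 1e-15 in that range).
#' Needed for the exponential-filter/EQ convolution in the near-delta
#' regime where the decay-lengthscale product is large.
#'
#' @param x numeric vector (any sign; large negative values overflow by
#'   nature of the function and return `Inf`).
#' @return numeric vector.
#' @export
erfcx <- function(x) {
  out <- numeric(length(x))
  small <- x <= 25
  if (any(small)) {
    xs <- x[small]
    out[small] <- exp(xs^2) * pracma::erfc(xs)
  }
  if (any(!small)) {
    xl <- x[!small]
    # erfcx(x) ~ 1/(x sqrt(pi)) * sum_n (-1)^n (2n-1)!! / (2x^2)^n
    inv2x2 <- 1 / (2 * xl^2)
    term <- rep(1, length(xl))
    s <- rep(1, length(xl))
    for (n in 1:8) {
      term <- -term * (2 * n - 1) * inv2x2
      s <- s + term
    }
    out[!small] <- s / (xl * sqrt(pi))
  }
  out
}

# ---- parameter flattening --------------------------------------------------
# Trainable parameters live in nested named lists of numeric arrays. The
# optimiser works on a flat double vector; these helpers convert both ways.

flatten_params <- function(p) {
  if (is.numeric(p)) return(as.numeric(p))
  unlist(lapply(p, flatten_params), use.names = FALSE)
}

unflatten_params <- function(vec, template) {
  res <- rec_unflatten(vec, template, 1L)
  stopifnot(res$pos == length(vec) + 1L)
  res$value
}

rec_unflatten <- function(vec, template, pos) {
  if (is.numeric(template)) {
    n <- length(template)
    v <- vec[pos:(pos + n - 1L)]
    if (!is.null(dim(template))) dim(v) <- dim(template)
    return(list(value = v, pos = pos + n))
  }
  out <- template
  for (i in seq_along(template)) {
    r <- rec_unflatten(vec, template[[i]], pos)
    out[[i]] <- r$value
    pos <- r$pos
  }
  list(value = out, pos = pos)
}

# Elementwise sum of two parameter structures (used to accumulate gradients).
params_add <- function(a, b) {
  if (is.numeric(a)) return(a + b)
  out <- a
  for (i in seq_along(a)) out[[i]] <- params_add(a[[i]], b[[i]])
  out
}

# Structure of zeros matching a parameter template.
params_zero <- function(p) {
  if (is.numeric(p)) {
    z <- p
    z[] <- 0
    return(z)
  }
  out <- p
  for (i in seq_along(p)) out[[i]] <- params_zero(p[[i]])
  out
}

params_scale <- function(p, s) {
  if (is.numeric(p)) return(p * s)
  out <- p
  for (i in seq_along(p)) out[[i]] <- params_scale(p[[i]], s)
  out
}

# ---- AdamW -----------------------------------------------------------------

adamw_init <- function(n) {
  list(m = numeric(n), v = numeric(n), t = 0L)
}

# One AdamW step on flat vectors; minimises. Decoupled weight decay is applied
# directly to the parameters (not through the moments).
adamw_step <- function(theta, grad, state, lr = 0.01, beta1 = 0.9,
                       beta2 = 0.999, eps = 1e-8, weight_decay = 0) {
  state$t <- state$t + 1L
  state$m <- beta1 * state$m + (1 - beta1) * grad
  state$v <- beta2 * state$v + (1 - beta2) * grad^2
  mhat <- state$m / (1 - beta1^state$t)
  vhat <- state$v / (1 - beta2^state$t)
  theta <- theta - lr * (mhat / (sqrt(vhat) + eps) + weight_decay * theta)
  list(theta = theta, state = state)
}

# ---- seeded RNG helpers ----------------------------------------------------

# Run `expr` under a local RNG stream seeded by `seed`, restoring the caller's
# RNG state afterwards. Keeps every stochastic component a pure function of
# its seed argument.
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# Derive a child seed from a base seed and an index, staying inside 32-bit
# signed integer range.
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(k) * 104729) %% 2147483647)
}
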