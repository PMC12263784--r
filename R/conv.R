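#' Exponential filter applied to a cosine basis function
#'
#' Closed form of \eqn{\int_{-\infty}^{x} e^{-\gamma(x-z)}
#' \cos(\theta z + \beta)\, dz}:
#' \deqn{\frac{\gamma\cos(\theta x + \beta) + \theta\sin(\theta x + \beta)}
#'       {\gamma^2 + \theta^2}.}
#' This is the response of the first-order system to one pathwise Fourier
#' basis function, used to map sampled latent paths analytically through the
#' layer convolution.
#'
#' @param gamma positive decay.
#' @param theta,beta frequency and phase.
#' @param x evaluation point(s).
#' @return numeric vector (vectorised over all arguments with recycling).
#' @examples
#' conv_cosine(2, 0, 0, 1)   # 1/gamma = 0.5
#' conv_cosine(1, 1, 0, 0)   # 0.5
#' @export
conv_cosine <- function(gamma, theta, beta, x) {
  if (any(gamma <= 0)) stop("`gamma` must be positive")
  arg <- theta * x + beta
  (gamma * cos(arg) + theta * sin(arg)) / (gamma^2 + theta^2)
}

#' Exponential filter applied to an EQ canonical basis function
#'
#' Closed form of \eqn{\int_{-\infty}^{x} e^{-\gamma(x-z)}
#' \exp(-(z - z_m)^2/\ell^2)\, dz}. Completing the square gives
#' \deqn{\frac{\sqrt{\pi}\,\ell}{2}\, e^{\gamma^2\ell^2/4 - \gamma a}\,
#'       \mathrm{erfc}\!\left(\frac{\gamma\ell}{2} - \frac{a}{\ell}\right),
#'       \qquad a = x - z_m,}
#' evaluated through the scaled complementary error function
#' (\eqn{(\sqrt{\pi}\ell/2) e^{-a^2/\ell^2}\, \mathrm{erfcx}(t)} for
#' \eqn{t \ge 0}) so that large \eqn{\gamma\ell} never overflows. This is
#' the response of the first-order system to one canonical (kernel) basis
#' function of the pathwise update term.
#'
#' @param gamma positive decay.
#' @param ell positive lengthscale.
#' @param x evaluation point(s).
#' @param z_m centre(s) of the canonical basis functions.
#' @return numeric vector (vectorised with recycling).
#' @export
conv_eq_canonical <- function(gamma, ell, x, z_m) {
  if (any(gamma <= 0)) stop("`gamma` must be positive")
  if (any(ell <= 0)) stop("`ell` must be positive")
  conv_eq_core(gamma, ell, x - z_m)$value
}

# Shared stable evaluation; a = x - z_m. Returns value and the Gaussian
# factor exp(-a^2/ell^2) reused by the derivative formulas.
conv_eq_core <- function(gamma, ell, a) {
  t <- gamma * ell / 2 - a / ell
  g <- exp(-(a / ell)^2)
  n <- max(length(t), length(g), length(gamma), length(ell))
  t <- rep_len(t, n); g <- rep_len(g, n)
  gam <- rep_len(gamma, n); el <- rep_len(ell, n); aa <- rep_len(a, n)
  val <- numeric(n)
  pos <- t >= 0
  if (any(pos)) {
    val[pos] <- (sqrt(pi) / 2) * el[pos] * g[pos] * erfcx(t[pos])
  }
  if (any(!pos)) {
    # here a > gamma*ell^2/2 so the exponent is negative: no overflow
    h <- gam[!pos]^2 * el[!pos]^2 / 4 - gam[!pos] * aa[!pos]
    val[!pos] <- (sqrt(pi) / 2) * el[!pos] * exp(h) * pracma::erfc(t[!pos])
  }
  list(value = val, gauss = g)
}

# Value and partial derivatives of conv_eq_canonical wrt gamma, x and ell.
# d/dx follows the defining ODE (C' = k(x, z_m) - gamma C); d/dgamma and
# d/dell differentiate the closed form.
conv_eq_grads <- function(gamma, ell, x, z_m) {
  a <- x - z_m
  core <- conv_eq_core(gamma, ell, a)
  I <- core$value; g <- core$gauss
  dgamma <- I * (gamma * ell^2 / 2 - a) - (ell^2 / 2) * g
  dx <- g - gamma * I
  dell <- I * (1 / ell + gamma^2 * ell / 2) - ell * g * (gamma / 2 + a / ell^2)
  list(value = I, dgamma = dgamma, dx = dx, dell = dell, gauss = g)
}
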