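# Brute-force quadrature oracles. These exist to validate the closed-form
# feature and convolution expressions in the test suite and the acceptance
# checks; they are never called on any training or prediction path.

#' Quadrature oracle for the first-order response feature
#'
#' Computes \eqn{\int_0^t e^{-\gamma(t-\tau)} e^{j\omega\tau} d\tau} by
#' adaptive quadrature on the real and imaginary parts separately. Test-only
#' counterpart of [rfrf_complex()].
#'
#' @param t,gamma,omega scalars; `gamma > 0`.
#' @param tol absolute tolerance passed to the quadrature routine.
#' @return complex scalar.
#' @export
rfrf_quadrature <- function(t, gamma, omega, tol = 1e-10) {
  stopifnot(length(t) == 1, gamma > 0)
  if (t == 0) return(0 + 0i)
  re <- stats::integrate(function(tau) exp(-gamma * (t - tau)) * cos(omega * tau),
                         0, t, rel.tol = tol, abs.tol = tol,
                         subdivisions = 1000L)$value
  im <- stats::integrate(function(tau) exp(-gamma * (t - tau)) * sin(omega * tau),
                         0, t, rel.tol = tol, abs.tol = tol,
                         subdivisions = 1000L)$value
  complex(real = re, imaginary = im)
}

#' Quadrature oracle for the latent force model covariance
#'
#' Evaluates the double convolution integral defining the covariance between
#' two outputs of a (shallow) latent force model,
#' \deqn{k_{f_d f_{d'}}(t,t') = \sum_q S_{d,q} S_{d',q}
#'   \int_{a}^{t}\! G_d(t-\tau) \int_{a}^{t'}\! G_{d'}(t'-\tau')
#'   k_q(\tau,\tau')\, d\tau' d\tau,}
#' with exponential Green's functions and EQ latent kernels, by adaptive 2-D
#' quadrature. The lower limit `a` is 0 for the classical formulation and
#' `-Inf` for the whole-history convolution used by the inducing-point model
#' (truncated where the filter mass is negligible). Test-only oracle.
#'
#' @param t,tp scalar inputs.
#' @param gamma_d,gamma_dp decays of the two output filters.
#' @param kernel a [latent_force_kernel()] for the latent forces.
#' @param sens_d,sens_dp per-force sensitivities, recycled to `kernel$q`.
#' @param lower lower integration limit, `0` or `-Inf`.
#' @param tol relative tolerance for the 2-D quadrature.
#' @return covariance value (numeric scalar).
#' @export
lfm_kernel_quadrature <- function(t, tp, gamma_d, gamma_dp = gamma_d,
                                  kernel = latent_force_kernel(),
                                  sens_d = 1, sens_dp = 1,
                                  lower = 0, tol = 1e-10) {
  stopifnot(gamma_d > 0, gamma_dp > 0)
  sens_d <- rep_len(sens_d, kernel$q)
  sens_dp <- rep_len(sens_dp, kernel$q)
  total <- 0
  for (qi in seq_len(kernel$q)) {
    ell <- kernel$lengthscale[qi]
    if (is.finite(lower)) {
      lo_t <- lower; lo_tp <- lower
    } else {
      # integrand negligible once the filters have decayed ~ e^-45
      lo_t <- t - 45 / gamma_d
      lo_tp <- tp - 45 / gamma_dp
    }
    if (t <= lo_t || tp <= lo_tp) next
    f <- function(tau, taup) {
      exp(-gamma_d * (t - tau) - gamma_dp * (tp - taup) -
            (tau - taup)^2 / ell^2)
    }
    val <- pracma::integral2(f, lo_t, t, lo_tp, tp, reltol = tol)$Q
    total <- total + sens_d[qi] * sens_dp[qi] * kernel$variance * val
  }
  total
}

#' Quadrature oracle for the filtered cosine convolution
#'
#' Computes \eqn{\int_{-\infty}^{x} e^{-\gamma(x-z)} \cos(\theta z + \beta)
#' dz} by summing adaptive quadrature over one oscillation period at a time
#' (the integrand decays geometrically, so the truncated tail is negligible).
#' Test-only counterpart of [conv_cosine()].
#'
#' @param gamma positive decay.
#' @param theta,beta frequency and phase of the cosine.
#' @param x upper limit.
#' @param tol per-segment absolute tolerance.
#' @return numeric scalar.
#' @export
conv_cosine_quadrature <- function(gamma, theta, beta, x, tol = 1e-12) {
  stopifnot(gamma > 0)
  width <- if (abs(theta) > 1e-12) 2 * pi / abs(theta) else 50 / gamma
  lo_final <- x - 60 / gamma
  total <- 0
  hi <- x
  while (hi > lo_final) {
    lo <- max(hi - width, lo_final)
    total <- total + stats::integrate(
      function(z) exp(-gamma * (x - z)) * cos(theta * z + beta),
      lo, hi, rel.tol = tol, abs.tol = tol, subdivisions = 200L)$value
    hi <- lo
  }
  total
}

#' Quadrature oracle for the filtered EQ-canonical convolution
#'
#' Computes \eqn{\int_{-\infty}^{x} e^{-\gamma(x-z)}
#' \exp(-(z - z_m)^2/\ell^2) dz} by adaptive quadrature with the lower limit
#' truncated where the Gaussian factor is negligible. Test-only counterpart
#' of [conv_eq_canonical()].
#'
#' @param gamma positive decay.
#' @param ell positive lengthscale of the EQ kernel.
#' @param x upper limit.
#' @param z_m centre of the canonical basis function.
#' @param tol absolute tolerance.
#' @return numeric scalar.
#' @export
conv_eq_quadrature <- function(gamma, ell, x, z_m, tol = 1e-12) {
  stopifnot(gamma > 0, ell > 0)
  lo <- min(x, z_m - 15 * ell) - 1
  stats::integrate(function(z) exp(-gamma * (x - z) - (z - z_m)^2 / ell^2),
                   lo, x, rel.tol = tol, abs.tol = tol,
                   subdivisions = 1000L)$value
}
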