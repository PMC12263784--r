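#' KL divergence between diagonal Gaussians
#'
#' Closed-form \eqn{D_{KL}[N(m_q, v_q) \| N(m_p, v_p)]} summed over
#' elements; the penalty term of the weight-space variational bound.
#'
#' @param m_q,v_q variational means and variances (vectors/arrays).
#' @param m_p,v_p prior means and variances (recycled).
#' @return nonnegative scalar, zero iff the distributions coincide.
#' @examples
#' kl_gaussian(1, 1, 0, 1)   # 0.5
#' kl_gaussian(0, 4, 0, 1)   # 0.5 * (4 - 1 - log 4)
#' @export
kl_gaussian <- function(m_q, v_q, m_p = 0, v_p = 1) {
  if (any(v_q <= 0) || any(v_p <= 0)) stop("variances must be positive")
  sum(0.5 * ((v_q + (m_q - m_p)^2) / v_p - 1 + log(v_p) - log(v_q)))
}

#' KL divergence between full-covariance Gaussians
#'
#' \eqn{D_{KL}[N(\mu, \Sigma) \| N(0, K)]} for SPD matrices, the per-layer
#' penalty of the inducing-point variational bound, with the sparse-GP prior
#' \eqn{N(0, K_{uu})} over inducing outputs.
#'
#' @param mu variational mean vector.
#' @param sigma variational covariance (SPD).
#' @param k prior covariance (SPD).
#' @return nonnegative scalar.
#' @export
kl_mvn <- function(mu, sigma, k) {
  m <- length(mu)
  ck <- chol(k)
  cs <- chol(sigma)
  kinv_sigma <- chol2inv(ck) %*% sigma
  quad <- sum(backsolve(ck, mu, transpose = TRUE)^2)
  0.5 * (sum(diag(kinv_sigma)) + quad - m +
           2 * sum(log(diag(ck))) - 2 * sum(log(diag(cs))))
}
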