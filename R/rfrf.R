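#' Random Fourier response feature for the first-order ODE
#'
#' The complex feature
#' \deqn{\phi(t, \gamma, \omega) = \frac{e^{j\omega t} - e^{-\gamma t}}
#'       {\gamma + j\omega}}
#' is the convolution \eqn{\int_0^t e^{-\gamma(t-\tau)} e^{j\omega\tau}
#' d\tau} of a Fourier basis function with the exponential Green's function,
#' i.e. the response of the first-order system to a random Fourier input.
#' A latent force kernel built from these features inherits the ODE's
#' dynamics. Conjugate symmetry \eqn{\phi(t,\gamma,-\omega) =
#' \overline{\phi(t,\gamma,\omega)}} holds because the filter is real.
#'
#' @param t numeric vector of inputs (any real; negative values are the
#'   analytic continuation met by inner layers).
#' @param gamma positive decay of the Green's function.
#' @param omega numeric vector of spectral frequencies, recycled against `t`.
#' @return complex vector.
#' @examples
#' rfrf_complex(0, 1, 2.5)          # exactly 0+0i
#' rfrf_complex(1, 1, 0)            # 1 - exp(-1)
#' @export
rfrf_complex <- function(t, gamma, omega) {
  stopifnot(gamma > 0)
  (exp(1i * omega * t) - exp(-gamma * t)) / complex(real = gamma, imaginary = omega)
}

#' Realify a complex feature vector
#'
#' Stacks the real parts then the imaginary parts, preserving order within
#' each half, so that real inner products of realified vectors equal the
#' real part of the corresponding complex inner products
#' \eqn{\langle a, \bar b\rangle}.
#'
#' @param phic complex vector or matrix (features in columns).
#' @return numeric vector of doubled length, or matrix of doubled width.
#' @export
rfrf_realify <- function(phic) {
  if (is.matrix(phic)) return(cbind(Re(phic), Im(phic)))
  c(Re(phic), Im(phic))
}

#' Multi-dimensional random Fourier response features
#'
#' For an input vector \eqn{x \in R^p}, per-dimension feature vectors are
#' computed with their own decay and spectral block and summed:
#' \eqn{\phi^c(x) = \sum_m \phi^c(x_m, \gamma_m, \omega_m)}. The per-force
#' scaling \eqn{\sqrt{S_q^2 / N_{RF}}} is applied here, exactly once.
#'
#' @param x numeric matrix `n` x `p` (or vector, treated as `n` x 1).
#' @param gamma positive decays, length `p`.
#' @param omega list of length `p`; element `m` is the `q` x `n_rf` spectral
#'   block for dimension `m`.
#' @param sensitivity per-force sensitivities \eqn{S_q}, length `q`.
#' @return complex matrix `n` x `(q * n_rf)`, features in (force, frequency)
#'   lexicographic order.
#' @export
rfrf_multidim <- function(x, gamma, omega, sensitivity = 1) {
  x <- as.matrix(x)
  p <- ncol(x)
  if (!is.list(omega)) omega <- list(omega)
  if (length(omega) != p || length(gamma) != p) {
    stop("need one decay and one spectral block per input dimension")
  }
  q <- nrow(omega[[1]]); n_rf <- ncol(omega[[1]])
  sensitivity <- rep_len(sensitivity, q)
  acc <- matrix(0 + 0i, nrow(x), q * n_rf)
  for (m in seq_len(p)) {
    om <- as.vector(t(omega[[m]])) # (q, s) lexicographic
    E <- exp(1i * outer(x[, m], om))
    D <- exp(-gamma[m] * x[, m])
    denom <- complex(real = gamma[m], imaginary = om)
    acc <- acc + sweep(E - D, 2, denom, "/")
  }
  scale <- rep(sensitivity / sqrt(n_rf), each = n_rf)
  sweep(acc, 2, scale, "*")
}

#' Random Fourier features of the EQ kernel
#'
#' The baseline deep-GP feature map
#' \eqn{\Phi = \sqrt{\sigma^2/N_{RF}}\,[\cos(F\Omega), \sin(F\Omega)]};
#' \eqn{\Phi\Phi^\top} is an unbiased estimator of the EQ kernel matrix when
#' the columns of \eqn{\Omega} are drawn from the kernel's spectral density.
#'
#' @param f numeric matrix `n` x `p` of inputs.
#' @param omega numeric matrix `p` x `n_rf` of spectral frequencies.
#' @param variance nonnegative marginal variance \eqn{\sigma^2}.
#' @return numeric matrix `n` x `2 n_rf`.
#' @export
eq_rff <- function(f, omega, variance = 1) {
  if (variance < 0) stop("variance must be nonnegative")
  f <- as.matrix(f)
  stopifnot(ncol(f) == nrow(omega))
  z <- f %*% omega
  sqrt(variance / ncol(omega)) * cbind(cos(z), sin(z))
}

# ---- internal layer feature map with backward pass -------------------------
# A feature block is a list with:
#   type   "lfm" or "eq"
#   gamma  length-p decays (lfm)
#   Omega  p x J matrix, J = q*n_rf (lfm, lexicographic) or p x n_rf (eq)
#   sens   length-q sensitivities (lfm)
#   sigma2 marginal variance (eq)
#   n_rf, q
# Returns phi (n x 2J realified) plus a cache for the backward pass.

feature_forward <- function(X, block) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (block$type == "lfm") {
    J <- block$q * block$n_rf
    stopifnot(ncol(block$Omega) == J, nrow(block$Omega) == p)
    acc <- matrix(0 + 0i, n, J)
    Es <- vector("list", p); Ds <- vector("list", p); phis <- vector("list", p)
    for (m in seq_len(p)) {
      om <- block$Omega[m, ]
      E <- exp(1i * (X[, m] %o% om))
      D <- exp(-block$gamma[m] * X[, m])
      denom <- complex(real = block$gamma[m], imaginary = om)
      ph <- sweep(E - D, 2, denom, "/")
      acc <- acc + ph
      Es[[m]] <- E; Ds[[m]] <- D; phis[[m]] <- ph
    }
    scale <- rep(block$sens / sqrt(block$n_rf), each = block$n_rf)
    phic <- sweep(acc, 2, scale, "*")
    phi <- cbind(Re(phic), Im(phic))
    list(phi = phi,
         cache = list(type = "lfm", X = X, block = block, Es = Es, Ds = Ds,
                      phis = phis, acc = acc, scale = scale))
  } else {
    Z <- X %*% block$Omega
    sc <- sqrt(block$sigma2 / block$n_rf)
    phi <- sc * cbind(cos(Z), sin(Z))
    list(phi = phi,
         cache = list(type = "eq", X = X, block = block, Z = Z, sc = sc))
  }
}

# dphi: n x 2J gradient of the loss wrt the realified features.
# Returns gradients wrt X, gamma (lfm), Omega, sens (lfm) / sigma2 (eq).
feature_backward <- function(cache, dphi) {
  if (cache$type == "lfm") {
    block <- cache$block
    J <- block$q * block$n_rf
    dA <- dphi[, seq_len(J), drop = FALSE]
    dB <- dphi[, J + seq_len(J), drop = FALSE]
    # a*Re(u) + b*Im(u) = Re((a - jb) u)
    G <- sweep(matrix(complex(real = dA, imaginary = -dB), nrow(dA), J),
               2, cache$scale, "*")
    X <- cache$X
    p <- ncol(X)
    dX <- matrix(0, nrow(X), p)
    dgamma <- numeric(p)
    dOmega <- matrix(0, p, J)
    for (m in seq_len(p)) {
      om <- block$Omega[m, ]
      denom <- complex(real = block$gamma[m], imaginary = om)
      E <- cache$Es[[m]]; D <- cache$Ds[[m]]; ph <- cache$phis[[m]]
      iOmE <- sweep(E, 2, 1i * om, "*")
      dphidx <- sweep(iOmE + block$gamma[m] * D, 2, denom, "/")
      dX[, m] <- rowSums(Re(G * dphidx))
      dphidg <- sweep(X[, m] * D - ph, 2, denom, "/")
      dgamma[m] <- sum(Re(G * dphidg))
      dphido <- sweep(1i * (X[, m] * E - ph), 2, denom, "/")
      dOmega[m, ] <- colSums(Re(G * dphido))
    }
    # sensitivity gradient: phi = scale * acc, scale_j = S_q / sqrt(n_rf)
    Gs <- matrix(complex(real = dA, imaginary = -dB), nrow(dA), J)
    per_feature <- colSums(Re(Gs * cache$acc)) / sqrt(block$n_rf)
    dsens <- as.numeric(tapply(per_feature,
                               rep(seq_len(block$q), each = block$n_rf), sum))
    list(dX = dX, dgamma = dgamma, dOmega = dOmega, dsens = dsens)
  } else {
    block <- cache$block
    J <- block$n_rf
    dA <- dphi[, seq_len(J), drop = FALSE]
    dB <- dphi[, J + seq_len(J), drop = FALSE]
    Z <- cache$Z
    dZ <- cache$sc * (-dA * sin(Z) + dB * cos(Z))
    dX <- tcrossprod(dZ, block$Omega)
    dOmega <- crossprod(cache$X, dZ)
    # phi = sqrt(sigma2/n_rf) * [...]; d phi / d sigma2 = phi / (2 sigma2)
    dsigma2 <- if (cache$block$sigma2 > 0) {
      sum(dphi * (cache$sc * cbind(cos(Z), sin(Z)))) / (2 * block$sigma2)
    } else 0
    list(dX = dX, dgamma = NULL, dOmega = dOmega, dsigma2 = dsigma2)
  }
}
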