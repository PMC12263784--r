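#' Exponentiated quadratic kernel
#'
#' \eqn{k(x, x') = \sigma^2 \exp(-\|x - x'\|^2 / \ell^2)}. This is the
#' parameterisation whose spectral density (by Bochner's theorem) is the
#' zero-mean Gaussian with variance \eqn{2/\ell^2} per input dimension; the
#' random-feature machinery in the package samples frequencies from exactly
#' that law.
#'
#' @param x,y numeric matrices (rows are points) or vectors (treated as
#'   one-dimensional points).
#' @param lengthscale positive lengthscale \eqn{\ell}.
#' @param variance marginal variance \eqn{\sigma^2} (default 1).
#' @return the `nrow(x)` by `nrow(y)` kernel matrix.
#' @export
eq_kernel <- function(x, y = x, lengthscale = 1, variance = 1) {
  stopifnot(lengthscale > 0, variance >= 0)
  x <- as.matrix(x); y <- as.matrix(y)
  stopifnot(ncol(x) == ncol(y))
  d2 <- outer(rowSums(x^2), rowSums(y^2), "+") - 2 * tcrossprod(x, y)
  d2[d2 < 0] <- 0
  variance * exp(-d2 / lengthscale^2)
}

#' Latent force kernel description
#'
#' Bundles the hyperparameters of the EQ Gaussian-process priors placed over
#' the latent forces of a layer: one lengthscale per force, a shared marginal
#' variance, and the force count `q`.
#'
#' @param lengthscale positive lengthscales, recycled to length `q`.
#' @param variance nonnegative marginal variance.
#' @param q number of latent forces.
#' @return an object of class `latent_force_kernel`.
#' @export
latent_force_kernel <- function(lengthscale = 1, variance = 1, q = 1L) {
  q <- as.integer(q)
  stopifnot(q >= 1)
  lengthscale <- rep_len(as.numeric(lengthscale), q)
  if (any(lengthscale <= 0)) stop("lengthscales must be positive")
  if (variance < 0) stop("variance must be nonnegative")
  structure(list(lengthscale = lengthscale, variance = variance, q = q),
            class = "latent_force_kernel")
}

#' Sample spectral frequencies of an EQ kernel
#'
#' Draws random frequencies from the spectral density
#' \eqn{N(0, 2/\ell_q^2)} of each latent force's EQ kernel. Frequencies are
#' returned in (force, feature) lexicographic order so that feature layouts
#' are reproducible across checkpoints.
#'
#' @param kernel a [latent_force_kernel()].
#' @param n_rf number of random features per force.
#' @param seed optional integer seed; when given, sampling is a pure function
#'   of it.
#' @return a numeric matrix of shape `q` x `n_rf`.
#' @export
sample_spectral <- function(kernel, n_rf, seed = NULL) {
  stopifnot(inherits(kernel, "latent_force_kernel"), n_rf >= 1)
  draw <- function() {
    m <- matrix(stats::rnorm(kernel$q * n_rf), nrow = kernel$q)
    m * (sqrt(2) / kernel$lengthscale) # scales row q by its force's spectral sd
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}
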