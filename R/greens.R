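#' First-order ODE Green's function
#'
#' Constructs the impulse response \eqn{G(x) = e^{-\gamma x}} of the linear
#' operator \eqn{d/dt + \gamma}. This exponential filter is the mechanistic
#' ingredient of every latent force layer in the package: outputs are
#' convolutions of latent Gaussian-process forces with `G`. Its total mass on
#' \eqn{[0, \infty)} is \eqn{1/\gamma}, so large decays approach a Dirac
#' impulse (up to that normalisation) and a layer collapses towards its
#' latent EQ process.
#'
#' @param gamma positive decay rate (scalar or vector, one per input
#'   dimension).
#' @return an object of class `greens_first_order`.
#' @examples
#' g <- greens_first_order(2)
#' greens_eval(g, 0)      # 1
#' greens_eval(g, 0.5)    # exp(-1)
#' @export
greens_first_order <- function(gamma) {
  gamma <- as.numeric(gamma)
  if (length(gamma) < 1 || any(!is.finite(gamma)) || any(gamma <= 0)) {
    stop("`gamma` must be positive and finite")
  }
  structure(list(gamma = gamma), class = "greens_first_order")
}

#' Evaluate a Green's function
#'
#' @param greens a `greens_first_order` object.
#' @param x numeric vector of evaluation points.
#' @return `exp(-gamma * x)`; when `greens` holds several decays the result is
#'   a matrix with one column per decay (the separable multi-dimensional
#'   filter is the row-wise product of these columns).
#' @export
greens_eval <- function(greens, x) {
  stopifnot(inherits(greens, "greens_first_order"))
  g <- greens$gamma
  if (length(g) == 1L) return(exp(-g * x))
  outer(x, g, function(xx, gg) exp(-gg * xx))
}
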