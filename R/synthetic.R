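# Generators: the toy compositional ODE system, prior-sampled multi-output
# nonstationary signals, and the split protocols used in the experiments.

#' Specification of the toy compositional ODE system
#'
#' Two first-order stages driven by a shared sinusoidal latent force:
#' \deqn{f_1(t) = \int_0^t e^{-\gamma_1 (t-\tau)} u(\tau)\, d\tau, \qquad
#'       f_2(t) = \int_0^{f_1(t)} e^{-\gamma_2 (f_1(t)-\tau)} u(\tau)\, d\tau,}
#' observed as \eqn{y_2 = f_2 + \epsilon}. The second stage integrates up to
#' the value of the first, making the composition strongly nonlinear. The
#' default latent force is \eqn{u(t) = \cos(0.5 t) + 6\sin(3 t)}, stored as
#' a harmonic table so both stages evaluate in closed form.
#'
#' @param harmonics data frame with columns `type` ("cos"/"sin"), `amp`,
#'   `freq` describing \eqn{u(t) = \sum_k a_k \cos/\sin(\omega_k t)}; set to
#'   `NULL` to use a general `u_fun` via adaptive quadrature.
#' @param u_fun latent force as a function of `t` (only used when
#'   `harmonics` is `NULL`).
#' @param gamma1,gamma2 positive decays of the two stages.
#' @param noise_sd observation noise standard deviation; `NULL` = 5% of the
#'   empirical standard deviation of \eqn{f_2}.
#' @param t_max,n_steps regular time grid \eqn{[0, t_{max}]}.
#' @param seed seed for the observation noise.
#' @return an object of class `toy_system_spec`.
#' @export
toy_system_spec <- function(harmonics = data.frame(
                              type = c("cos", "sin"),
                              amp = c(1, 6),
                              freq = c(0.5, 3)),
                            u_fun = NULL,
                            gamma1 = 1, gamma2 = 1, noise_sd = NULL,
                            t_max = 15, n_steps = 500, seed = 1) {
  stopifnot(gamma1 > 0, gamma2 > 0, is.null(noise_sd) || noise_sd >= 0,
            t_max > 0, n_steps >= 2)
  if (is.null(harmonics) && is.null(u_fun)) {
    stop("either `harmonics` or `u_fun` must be given")
  }
  if (!is.null(harmonics)) {
    stopifnot(all(harmonics$type %in% c("cos", "sin")))
    u_fun <- function(t) {
      out <- 0
      for (k in seq_len(nrow(harmonics))) {
        w <- harmonics$freq[k]; a <- harmonics$amp[k]
        out <- out + if (harmonics$type[k] == "cos") a * cos(w * t) else
          a * sin(w * t)
      }
      out
    }
  }
  structure(list(harmonics = harmonics, u_fun = u_fun,
                 gamma1 = gamma1, gamma2 = gamma2, noise_sd = noise_sd,
                 t_max = t_max, n_steps = n_steps, seed = seed),
            class = "toy_system_spec")
}

# Closed-form response of a first-order filter to one harmonic, from zero
# initial condition: int_0^t exp(-gamma (t - tau)) cos/sin(w tau) d tau.
# Both sides satisfy h' = u(t) - gamma h with h(0) = 0, so the formula is
# valid for negative upper limits as well (signed orientation).
harmonic_response <- function(t, gamma, freq, type) {
  den <- gamma^2 + freq^2
  if (type == "cos") {
    (gamma * cos(freq * t) + freq * sin(freq * t) - gamma * exp(-gamma * t)) / den
  } else {
    (gamma * sin(freq * t) - freq * cos(freq * t) + freq * exp(-gamma * t)) / den
  }
}

# First-stage response at arbitrary (possibly negative) upper limits.
toy_stage <- function(spec, upper, gamma) {
  if (!is.null(spec$harmonics)) {
    out <- 0
    for (k in seq_len(nrow(spec$harmonics))) {
      out <- out + spec$harmonics$amp[k] *
        harmonic_response(upper, gamma, spec$harmonics$freq[k],
                          spec$harmonics$type[k])
    }
    out
  } else {
    vapply(upper, function(tt) {
      r <- stats::integrate(function(tau) {
        exp(-gamma * (tt - tau)) * spec$u_fun(tau)
      }, lower = 0, upper = tt, rel.tol = 1e-10, abs.tol = 1e-12)
      if (r$message != "OK") stop("quadrature failed: ", r$message)
      r$value
    }, numeric(1))
  }
}

#' Simulate the toy compositional ODE system
#'
#' Evaluates both stages on the regular time grid (closed form for harmonic
#' latent forces, adaptive quadrature otherwise) and adds observation noise
#' to the second-stage output only.
#'
#' @param spec a [toy_system_spec()].
#' @return data frame with columns `t`, `u`, `f1`, `f2`, `y2`.
#' @export
simulate_toy <- function(spec) {
  stopifnot(inherits(spec, "toy_system_spec"))
  t <- seq(0, spec$t_max, length.out = spec$n_steps)
  u <- spec$u_fun(t)
  f1 <- toy_stage(spec, t, spec$gamma1)
  f2 <- toy_stage(spec, f1, spec$gamma2)
  sd_n <- if (is.null(spec$noise_sd)) 0.05 * stats::sd(f2) else spec$noise_sd
  eps <- with_seed(spec$seed, stats::rnorm(length(t), sd = sd_n))
  data.frame(t = t, u = u, f1 = f1, f2 = f2, y2 = f2 + eps)
}

#' Simulate correlated nonstationary multi-output signals
#'
#' Draws from the prior of a two-layer inducing-point deep latent force
#' model (zero inducing points, pure pathwise prior) with per-output
#' decays, giving smooth pulse-like signals reminiscent of physiological
#' waveform channels. With `shared_latents = TRUE` all outputs are driven
#' by the same latent paths and are therefore correlated; otherwise each
#' output gets independent latents. Ground-truth latent paths and hidden
#' activations are returned for recovery tests.
#'
#' @param n_outputs number of output channels.
#' @param n_steps grid length (>= 100).
#' @param t_max end of the time grid.
#' @param gamma_out per-output decays of the output layer (recycled).
#' @param lengthscale latent lengthscale of both layers (on the unit-scaled
#'   time axis).
#' @param noise_sd observation noise standard deviation.
#' @param shared_latents share latent forces across outputs.
#' @param seed integer seed; fixed seed gives bitwise-identical output.
#' @return list with `data` (data frame `t`, `y1..yD`), `f` (noiseless
#'   outputs), `hidden` (first-layer activations), `latents` (layer-1
#'   latent path on the grid), `hidden_var` (analytic marginal variance of
#'   each hidden channel) and the generator settings.
#' @export
simulate_charis_like <- function(n_outputs = 3, n_steps = 1000, t_max = 10,
                                 gamma_out = c(3, 8, 20),
                                 lengthscale = 0.06, noise_sd = 0.02,
                                 shared_latents = TRUE, seed = 1) {
  stopifnot(n_steps >= 100, n_outputs >= 1, noise_sd >= 0)
  t <- seq(0, t_max, length.out = n_steps)
  xs <- matrix(t / t_max) # unit-scaled input
  gam <- rep_len(gamma_out, n_outputs)
  build <- function(d_out, gams, sd_) {
    m <- dlfm_vip(1, d_out, n_layers = 2, hidden_width = d_out,
                  m_inducing = 0, b_basis = 512, gamma = 5,
                  lengthscale = lengthscale, seed = sd_)
    m$layers[[2]]$rho_gamma <- matrix(softplus_inv(gams), d_out, d_out)
    m
  }
  one_draw <- function(model) {
    draw <- vip_draw_eps(model)
    reals <- lapply(model$layers, function(lay) {
      lapply(lay$forces, force_realise, jitter = model$jitter)
    })
    fw1 <- vip_layer_forward(model$layers[[1]], reals[[1]], xs, draw[[1]])
    fw2 <- vip_layer_forward(model$layers[[2]], reals[[2]], fw1$output,
                             draw[[2]])
    th <- draw[[1]][[1]]$eps_theta * (sqrt(2) / reals[[1]][[1]]$ell)
    lat <- sqrt(2 / model$layers[[1]]$B) *
      drop(cos(xs %*% t(th) + matrix(draw[[1]][[1]]$beta, n_steps,
                                     model$layers[[1]]$B, byrow = TRUE)) %*%
             draw[[1]][[1]]$w)
    list(hidden = fw1$output, f = fw2$output, latent = lat,
         a1 = model$layers[[1]]$a, ell1 = reals[[1]][[1]]$ell,
         gamma1 = softplus(model$layers[[1]]$rho_gamma))
  }
  res <- with_seed(seed, {
    if (shared_latents) {
      one_draw(build(n_outputs, gam, derive_seed(seed, 17)))
    } else {
      parts <- lapply(seq_len(n_outputs), function(d) {
        one_draw(build(1, gam[d], derive_seed(seed, 31 + d)))
      })
      list(hidden = do.call(cbind, lapply(parts, `[[`, "hidden")),
           f = do.call(cbind, lapply(parts, `[[`, "f")),
           latent = parts[[1]]$latent,
           a1 = do.call(rbind, lapply(parts, `[[`, "a1")),
           ell1 = parts[[1]]$ell1,
           gamma1 = do.call(rbind, lapply(parts, `[[`, "gamma1")))
    }
  })
  noise <- with_seed(derive_seed(seed, 997),
                     matrix(stats::rnorm(n_steps * n_outputs, sd = noise_sd),
                            n_steps, n_outputs))
  y <- res$f + noise
  colnames(y) <- paste0("y", seq_len(n_outputs))
  # analytic marginal variance of each hidden channel: sum_q a_dq^2 *
  # marginal variance of the whole-history convolution of a unit EQ process
  v_conv <- sqrt(pi) * res$ell1 / (2 * res$gamma1[, 1]) *
    erfcx(res$gamma1[, 1] * res$ell1 / 2)
  hidden_var <- rowSums(res$a1^2) * v_conv
  list(data = data.frame(t = t, y), f = res$f, hidden = res$hidden,
       latents = res$latent, hidden_var = hidden_var,
       settings = list(n_outputs = n_outputs, n_steps = n_steps,
                       t_max = t_max, gamma_out = gam,
                       lengthscale = lengthscale, noise_sd = noise_sd,
                       shared_latents = shared_latents, seed = seed))
}

# ---- split protocols -------------------------------------------------------

#' Train/test split specification
#'
#' @param mode `"imputation"` (remove non-overlapping blocks per output),
#'   `"extrapolation"` (hold out everything after a boundary index) or
#'   `"random"` (random points per output).
#' @param block_length,n_blocks imputation block geometry (also the number
#'   of random test points: `block_length * n_blocks`).
#' @param boundary last training index for extrapolation (`NULL` = hold out
#'   the final 25 points).
#' @param seed seed for the random placements.
#' @return an object of class `split_spec`.
#' @export
split_spec <- function(mode = c("imputation", "extrapolation", "random"),
                       block_length = 150, n_blocks = 1, boundary = NULL,
                       seed = 1) {
  mode <- match.arg(mode)
  stopifnot(block_length >= 1, n_blocks >= 1)
  structure(list(mode = mode, block_length = block_length,
                 n_blocks = n_blocks, boundary = boundary, seed = seed),
            class = "split_spec")
}

#' Build per-output train/test masks
#'
#' @param n_steps series length (or a data frame whose rows are counted).
#' @param n_outputs number of outputs.
#' @param spec a [split_spec()].
#' @return logical matrix `n_steps` x `n_outputs`; `TRUE` marks held-out
#'   (test) entries.
#' @export
make_split <- function(n_steps, n_outputs, spec) {
  stopifnot(inherits(spec, "split_spec"))
  if (is.data.frame(n_steps)) n_steps <- nrow(n_steps)
  n <- as.integer(n_steps)
  mask <- matrix(FALSE, n, n_outputs)
  if (spec$mode == "extrapolation") {
    b <- if (is.null(spec$boundary)) n - 25L else as.integer(spec$boundary)
    if (b < 1 || b >= n) stop("boundary must lie strictly inside the series")
    mask[(b + 1):n, ] <- TRUE
    return(mask)
  }
  n_test <- spec$block_length * spec$n_blocks
  if (n_test >= n - 2L) {
    stop("requested ", n_test, " test points but the series has only ",
         n, " steps")
  }
  with_seed(spec$seed, {
    for (d in seq_len(n_outputs)) {
      if (spec$mode == "random") {
        mask[sample.int(n, n_test), d] <- TRUE
      } else {
        # non-overlapping interior blocks (first and last observation always
        # retained, so every gap has context on both sides): distribute the
        # free space between and around the blocks uniformly at random
        free <- n - 2L - n_test
        cuts <- sort(stats::runif(spec$n_blocks))
        gaps <- floor(cuts * free)
        starts <- gaps + (seq_len(spec$n_blocks) - 1L) * spec$block_length + 2L
        for (s in starts) {
          mask[s:(s + spec$block_length - 1L), d] <- TRUE
        }
      }
    }
  })
  mask
}

#' Apply a split mask to a target matrix
#'
#' Returns the training view of `y`: held-out entries become `NA` (the
#' fitting routines exclude `NA` targets from the likelihood).
#'
#' @param y numeric matrix of targets.
#' @param mask logical matrix from [make_split()].
#' @return `y` with test entries set to `NA`.
#' @export
apply_split <- function(y, mask) {
  y <- as.matrix(y)
  stopifnot(all(dim(y) == dim(mask)))
  y[mask] <- NA
  y
}
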