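#' Hyperparameters of the parabola-extrapolation generative model
#'
#' Bundles the full generative parameter set: the bimodal prior over the
#' quadratic parameter \eqn{w} (modes at \eqn{\pm\mu_\pi}, per-mode standard
#' deviation \eqn{\sigma_\pi}, mixing coefficient \eqn{c} for the upward
#' mode), the generative noise \eqn{\sigma_g} applied to the y-coordinates of
#' the four stimulus dots, the x-design, and the probe location \eqn{x^\star}.
#'
#' The defaults are the main-experiment values: \eqn{\mu_\pi = 1},
#' \eqn{\sigma_\pi = 0.1}, \eqn{c = 1/2}, fixed x-positions
#' \eqn{(-0.3, -0.1, 0.1, 0.3)} and \eqn{x^\star = 2}. The second experiment
#' uses \eqn{\sigma_\pi = 0.5} with a jittered x-design (see
#' [x_design_jitter()]).
#'
#' @param mu_pi location of the positive prior mode (the negative mode sits at
#'   \code{-mu_pi}).
#' @param sigma_pi standard deviation of each prior mode; must be positive.
#' @param c_prior mixing coefficient of the positive (upward-parabola) mode,
#'   in \eqn{[0, 1]}.
#' @param sigma_g standard deviation of the generative noise added to the
#'   stimulus y-coordinates; non-negative.
#' @param x_design either a strictly increasing numeric vector of exactly four
#'   x-positions, or a jitter rule from [x_design_jitter()].
#' @param x_star probe x-position at which the extrapolated value is reported.
#' @return An object of class \code{"hyper_params"}.
#' @examples
#' hyper_params()                        # experiment-1 defaults, sigma_g = 0.1
#' hyper_params(sigma_g = 0.4)
#' hyper_params(sigma_pi = 0.5, x_design = x_design_jitter())
#' @export
hyper_params <- function(mu_pi = 1, sigma_pi = 0.1, c_prior = 0.5,
                         sigma_g = 0.1,
                         x_design = c(-0.3, -0.1, 0.1, 0.3),
                         x_star = 2) {
  if (!is.finite(sigma_pi) || sigma_pi <= 0) stop("sigma_pi must be > 0")
  if (!is.finite(sigma_g) || sigma_g < 0) stop("sigma_g must be >= 0")
  if (!is.finite(c_prior) || c_prior < 0 || c_prior > 1)
    stop("c_prior must lie in [0, 1]")
  if (is.numeric(x_design)) {
    if (length(x_design) != 4L) stop("a fixed x_design must have 4 entries")
    if (any(diff(x_design) <= 0)) stop("x_design must be strictly increasing")
  } else if (!inherits(x_design, "x_design_jitter")) {
    stop("x_design must be a numeric vector of length 4 or an x_design_jitter rule")
  }
  structure(list(mu_pi = mu_pi, sigma_pi = sigma_pi, c_prior = c_prior,
                 sigma_g = sigma_g, x_design = x_design, x_star = x_star),
            class = "hyper_params")
}

#' Jittered x-design rule
#'
#' The second experiment draws the four x-positions from Gaussians with means
#' \code{(-0.18, -0.09, 0, 0.09)} and standard deviation 0.09, resampling
#' whenever any two points end up closer than the minimum spacing of 0.1.
#'
#' @param means Gaussian means of the four x-positions.
#' @param sd common standard deviation of the jitter.
#' @param min_spacing smallest admissible pairwise distance between
#'   x-positions.
#' @param max_attempts resampling budget per stimulus before an error signals
#'   an infeasible design.
#' @return An object of class \code{"x_design_jitter"}.
#' @export
x_design_jitter <- function(means = c(-0.18, -0.09, 0, 0.09), sd = 0.09,
                            min_spacing = 0.1, max_attempts = 10000L) {
  if (length(means) != 4L) stop("jitter rule needs 4 means")
  if (sd <= 0) stop("sd must be > 0")
  structure(list(means = means, sd = sd, min_spacing = min_spacing,
                 max_attempts = as.integer(max_attempts)),
            class = "x_design_jitter")
}

#' @export
print.hyper_params <- function(x, ...) {
  cat("Generative hyperparameters\n")
  cat(sprintf("  prior: modes at +/-%g, per-mode sd %g, upward weight %g\n",
              x$mu_pi, x$sigma_pi, x$c_prior))
  cat(sprintf("  generative noise sigma_g = %g, probe x* = %g\n",
              x$sigma_g, x$x_star))
  if (is.numeric(x$x_design)) {
    cat("  x-design: fixed at", paste(x$x_design, collapse = ", "), "\n")
  } else {
    cat(sprintf("  x-design: jittered (means %s, sd %g, min spacing %g)\n",
                paste(x$x_design$means, collapse = ", "),
                x$x_design$sd, x$x_design$min_spacing))
  }
  invisible(x)
}

#' Bimodal prior over the quadratic parameter as a Gaussian mixture
#'
#' \deqn{\pi(w) = c\,N(w; \mu_\pi, \sigma_\pi^2) +
#'   (1-c)\,N(w; -\mu_\pi, \sigma_\pi^2)}
#'
#' @param hyper a [hyper_params()] object.
#' @return A [gmix()] object over \eqn{w}.
#' @export
prior_w <- function(hyper) {
  stopifnot(inherits(hyper, "hyper_params"))
  gmix(c(hyper$c_prior, 1 - hyper$c_prior),
       c(hyper$mu_pi, -hyper$mu_pi),
       rep(hyper$sigma_pi^2, 2))
}

#' Motor-noise values of the seven main-experiment participants
#'
#' Participant-specific standard deviations of the internal (neural, decision
#' and motor-execution) noise, estimated from the 20 responses each
#' participant gave to the noise-free practice stimulus. Their mean, 0.48, is
#' the constant used for second-experiment participants, whose noise-free
#' responses were not collected.
#'
#' @return Named numeric vector of length 7.
#' @examples
#' round(mean(exp1_motor_noise()), 2)  # 0.48, the experiment-2 constant
#' @export
exp1_motor_noise <- function() {
  c(subj1 = 0.22, subj2 = 0.30, subj3 = 0.74, subj4 = 0.88,
    subj5 = 0.34, subj6 = 0.37, subj7 = 0.54)
}
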