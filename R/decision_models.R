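#' Response distribution under a decision rule
#'
#' Turns a posterior-predictive distribution over \eqn{y^\star} into a
#' distribution over the observed response \eqn{r} by composing the decision
#' rule with motor noise \eqn{p(r|y^\star) = N(r; y^\star, \sigma_m^2)}:
#' \describe{
#'   \item{\code{"sampling"}}{probability matching: the response is one draw
#'     from the predictive, so \eqn{p(r) = \int N(r; y, \sigma_m^2)\,
#'     p(y|\cdot)\,dy} — a closed-form Gaussian convolution that adds
#'     \eqn{\sigma_m^2} to every component variance. \code{sigma_m = 0} is the
#'     identity.}
#'   \item{\code{"loss"}}{squared-loss Bayesian decision theory: the response
#'     is the predictive mean, so motor noise is the only source of response
#'     variability and \eqn{p(r) = N(r; E[y], \sigma_m^2)}. The output is
#'     always unimodal, whatever the modality of the predictive; a bimodal
#'     predictive with modes at \eqn{\pm 4} collapses to a Gaussian centred at
#'     0. Requires \code{sigma_m > 0} for the density to exist.}
#' }
#'
#' @param pred a [gmix()] posterior predictive over \eqn{y^\star}.
#' @param sigma_m motor-noise standard deviation.
#' @param rule \code{"sampling"} or \code{"loss"}.
#' @param model_id optional model label carried on the result.
#' @return An object of class \code{"response_dist"}: list with
#'   \code{mixture} (a [gmix()] over \eqn{r}), \code{model_id},
#'   \code{rule}, \code{sigma_m}.
#' @export
response_distribution <- function(pred, sigma_m,
                                  rule = c("sampling", "loss"),
                                  model_id = NA_character_) {
  stopifnot(inherits(pred, "gmix"))
  rule <- match.arg(rule)
  if (!is.finite(sigma_m) || sigma_m < 0) stop("sigma_m must be >= 0")
  if (rule == "sampling") {
    mixture <- gmix_convolve(pred, sigma_m)
  } else {
    if (sigma_m <= 0)
      stop("the loss rule needs sigma_m > 0: motor noise is its only response variability")
    mixture <- gmix(1, gmix_mean(pred), sigma_m^2)
  }
  structure(list(mixture = mixture, model_id = model_id, rule = rule,
                 sigma_m = sigma_m),
            class = "response_dist")
}

#' @export
print.response_dist <- function(x, ...) {
  cat(sprintf("Response distribution (%s rule, sigma_m = %g, model %s)\n",
              x$rule, x$sigma_m, x$model_id))
  print(x$mixture)
  invisible(x)
}

#' Estimate a participant's motor noise from noise-free responses
#'
#' Uses the repeated responses to the (virtually) noiseless practice stimulus.
#' Residuals are taken about the true probe value
#' \eqn{y^\star = w\,x^{\star 2}}, and \eqn{\sigma_m} is half the 16--84
#' inter-percentile range of the residuals — for Gaussian residuals this
#' equals the standard deviation, and it is robust to outlying responses.
#'
#' @param responses numeric vector of at least two responses to the noiseless
#'   stimulus.
#' @param true_y_star the noiseless probe value of that stimulus.
#' @return An object of class \code{"motor_noise"}: list with \code{sigma_m}
#'   and \code{n}. Degenerate (zero-spread) response sets are floored at
#'   \code{1e-3} with a warning rather than failing the pipeline.
#' @examples
#' set.seed(1)
#' estimate_motor_noise(rnorm(20, 3.9, 0.3), true_y_star = 4)
#' @export
estimate_motor_noise <- function(responses, true_y_star) {
  responses <- as.numeric(responses)
  if (length(responses) < 2L) stop("need at least 2 responses")
  resid <- responses - true_y_star
  qs <- stats::quantile(resid, c(0.16, 0.84), names = FALSE)
  sigma_m <- (qs[2] - qs[1]) / 2
  if (sigma_m <= 0) {
    warning("zero-spread responses: flooring sigma_m at 1e-3")
    sigma_m <- 1e-3
  }
  structure(list(sigma_m = sigma_m, n = length(responses)),
            class = "motor_noise")
}

#' @export
print.motor_noise <- function(x, ...) {
  cat(sprintf("Motor noise sigma_m = %.4g (from %d responses)\n",
              x$sigma_m, x$n))
  invisible(x)
}

#' Sample responses from a response distribution
#'
#' i.i.d. draws: a component is chosen by weight, then a Gaussian draw is
#' taken from it.
#'
#' @param dist a [response_distribution()] result (or a bare [gmix()]).
#' @param n number of draws (at least 1).
#' @return Numeric vector of length \code{n}.
#' @export
sample_response <- function(dist, n) {
  g <- if (inherits(dist, "response_dist")) dist$mixture else dist
  stopifnot(inherits(g, "gmix"))
  if (n < 1L) stop("n must be >= 1")
  rgmix(n, g)
}
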