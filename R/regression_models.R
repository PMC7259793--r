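#' Likelihood summary statistics of a four-dot stimulus
#'
#' For the generative model \eqn{y_i = w x_i^2 + \epsilon_i},
#' \eqn{\epsilon_i \sim N(0, \sigma_g^2)}, the likelihood of \eqn{w} is
#' Gaussian in \eqn{w}: its maximiser is
#' \deqn{w_{ML} = \frac{\sum_i y_i x_i^2}{\sum_i x_i^4}}
#' and its variance (in \eqn{w}-space) is
#' \eqn{s^2 = \sigma_g^2 / \sum_i x_i^4}.
#'
#' @param stim a [stimulus()] object.
#' @param sigma_g generative noise standard deviation used by the observer;
#'   must be positive.
#' @return A list with \code{w_ml}, \code{s2}, \code{sum_x4}, \code{sum_yx2}
#'   and the residual sum of squares \code{rss} about the fitted parabola.
#' @export
likelihood_stats <- function(stim, sigma_g) {
  stopifnot(inherits(stim, "stimulus"))
  if (!is.finite(sigma_g) || sigma_g <= 0) stop("sigma_g must be > 0")
  sum_x4 <- sum(stim$x^4)
  if (sum_x4 <= 0) stop("degenerate design: all x_i are 0")
  sum_yx2 <- sum(stim$y * stim$x^2)
  w_ml <- sum_yx2 / sum_x4
  list(w_ml = w_ml, s2 = sigma_g^2 / sum_x4,
       sum_x4 = sum_x4, sum_yx2 = sum_yx2,
       rss = sum((stim$y - w_ml * stim$x^2)^2))
}

#' Posterior over the quadratic parameter
#'
#' Conjugate update of the two-component Gaussian-mixture prior against the
#' Gaussian likelihood. Each prior mode at \eqn{\pm\mu_\pi} yields a posterior
#' component with common variance
#' \deqn{v = \left(1/\sigma_\pi^2 + \textstyle\sum_i x_i^4 / \sigma_g^2\right)^{-1},}
#' mean \eqn{v (\pm\mu_\pi/\sigma_\pi^2 + \sum_i y_i x_i^2 / \sigma_g^2)}, and
#' weight proportional to the prior weight times the marginal evidence of that
#' mode, \eqn{N(w_{ML}; \pm\mu_\pi, \sigma_\pi^2 + s^2)}. Weights are
#' normalised in log space.
#'
#' @param stim a [stimulus()] object.
#' @param hyper a [hyper_params()] object.
#' @param sigma_g_used noise standard deviation the observer assumes; defaults
#'   to the hyperparameter value, and is replaced by the trial-by-trial
#'   estimate for the noise-estimating model variant.
#' @return An object of class \code{"w_posterior"}: list with \code{mixture}
#'   (a [gmix()] over \eqn{w}) and \code{log_evidence} \eqn{= \log p(D_j)}.
#' @export
posterior_w <- function(stim, hyper, sigma_g_used = hyper$sigma_g) {
  stopifnot(inherits(hyper, "hyper_params"))
  ls <- likelihood_stats(stim, sigma_g_used)
  sp2 <- hyper$sigma_pi^2
  v <- 1 / (1 / sp2 + ls$sum_x4 / sigma_g_used^2)
  mode_mu <- c(hyper$mu_pi, -hyper$mu_pi)
  means <- v * (mode_mu / sp2 + ls$sum_yx2 / sigma_g_used^2)
  log_prior_w <- log(c(hyper$c_prior, 1 - hyper$c_prior))
  log_mode_ev <- stats::dnorm(ls$w_ml, mode_mu, sqrt(sp2 + ls$s2), log = TRUE)
  lw <- log_prior_w + log_mode_ev
  mixture <- gmix_from_log_weights(lw, means, rep(v, 2))
  # p(D) = (2 pi sigma^2)^(-M/2) exp(-RSS / (2 sigma^2)) * sqrt(2 pi s2)
  #        * sum_k c_k N(w_ml; +/- mu_pi, sigma_pi^2 + s2)
  m <- max(lw)
  log_evidence <- -2 * log(2 * pi * sigma_g_used^2) - ls$rss / (2 * sigma_g_used^2) +
    0.5 * log(2 * pi * ls$s2) + m + log(sum(exp(lw - m)))
  structure(list(mixture = mixture, log_evidence = log_evidence,
                 sigma_g_used = sigma_g_used),
            class = "w_posterior")
}

#' @export
print.w_posterior <- function(x, ...) {
  cat("Posterior over the quadratic parameter w\n")
  print(x$mixture)
  cat(sprintf("log evidence = %.6g\n", x$log_evidence))
  invisible(x)
}

#' Maximum a posteriori estimate from a posterior mixture
#'
#' Evaluates the mixture density at both component means, takes the better
#' one, and refines it by one-dimensional numerical optimisation in a
#' neighbourhood of that component. An exact tie (symmetric posterior) breaks
#' deterministically to the positive mode, with attribute \code{tie = TRUE}
#' set on the result.
#'
#' @param posterior a [posterior_w()] result (or a bare [gmix()] over
#'   \eqn{w}).
#' @return The maximising \eqn{w} (numeric scalar, possibly with a \code{tie}
#'   attribute).
#' @export
map_estimate <- function(posterior) {
  g <- if (inherits(posterior, "w_posterior")) posterior$mixture else posterior
  stopifnot(inherits(g, "gmix"))
  ld <- dgmix(g$means, g, log = TRUE)
  tie <- length(ld) > 1L && abs(ld[1] - ld[2]) <= 1e-9
  best <- if (tie) which.max(g$means) else which.max(ld)
  sd_best <- sqrt(g$vars[best])
  opt <- stats::optimize(function(w) dgmix(w, g, log = TRUE),
                         interval = g$means[best] + c(-3, 3) * sd_best,
                         maximum = TRUE, tol = 1e-10)
  out <- if (opt$objective >= ld[best]) opt$maximum else g$means[best]
  if (tie) attr(out, "tie") <- TRUE
  out
}

#' Trial-by-trial estimate of the generative noise
#'
#' Maximum-likelihood residual estimate about the least-squares parabola
#' through the stimulus:
#' \deqn{\hat\sigma_g^2 = \frac{1}{M}\sum_{i=1}^{M}(y_i - w^\star x_i^2)^2,
#'   \quad w^\star = \frac{\sum_i y_i x_i^2}{\sum_i x_i^4},}
#' with \eqn{M = 4}. The divisor is \eqn{M} (not \eqn{M - 1}) because this is
#' the ML estimator with one fitted parameter; it is therefore biased
#' downward. No floor is applied here; consumers floor the value (see
#' [predictive()]).
#'
#' @param stim a [stimulus()] object.
#' @return \eqn{\hat\sigma_g \ge 0} (numeric scalar).
#' @export
estimate_sigma_g <- function(stim) {
  stopifnot(inherits(stim, "stimulus"))
  w_star <- sum(stim$y * stim$x^2) / sum(stim$x^4)
  sqrt(mean((stim$y - w_star * stim$x^2)^2))
}

#' Smallest generative-noise value used by the noise-estimating model
#'
#' Floor applied to [estimate_sigma_g()] inside [predictive()] so that
#' residual-free stimuli do not produce an infinitely precise likelihood; with
#' the floor the noise-estimating variant degenerates gracefully towards
#' maximum-likelihood-like certainty.
#' @keywords internal
SIGMA_G_FLOOR <- 1e-6

#' Posterior-predictive distribution of a regression model
#'
#' Closed-form predictive distribution over the probe value
#' \eqn{y^\star = w {x^\star}^2 + \epsilon} for the five regression models:
#' \describe{
#'   \item{\code{"PR"}}{prior regression, the null model: marginalises the
#'     prior, ignoring the stimulus. Components at \eqn{\pm\mu_\pi x^{\star 2}}
#'     with variance \eqn{\sigma_\pi^2 x^{\star 4} + \sigma_g^2} and weights
#'     \eqn{(c, 1-c)}.}
#'   \item{\code{"MLR"}}{maximum-likelihood regression:
#'     \eqn{N(w_{ML} x^{\star 2}, \sigma_g^2)}; no prior is used.}
#'   \item{\code{"MAPR"}}{maximum-a-posteriori regression:
#'     \eqn{N(w_{MAP} x^{\star 2}, \sigma_g^2)}; uses the prior only through
#'     the posterior mode.}
#'   \item{\code{"BR"}}{full Bayesian regression: pushes the posterior mixture
#'     over \eqn{w} through the probe, giving components with means
#'     \eqn{m_k x^{\star 2}}, variance \eqn{v x^{\star 4} + \sigma_g^2} and the
#'     posterior weights. The generative noise modulates the transition from a
#'     unimodal to a bimodal predictive.}
#'   \item{\code{"BRsigma"}}{Bayesian regression with trial-by-trial noise
#'     estimation: as \code{"BR"} with \eqn{\hat\sigma_g} from
#'     [estimate_sigma_g()] (floored at \code{1e-6}) substituted for
#'     \eqn{\sigma_g} in both the posterior precision and the predictive noise
#'     term.}
#' }
#'
#' @param model_id one of \code{"PR"}, \code{"MLR"}, \code{"MAPR"},
#'   \code{"BR"}, \code{"BRsigma"}.
#' @param stim a [stimulus()] object (ignored by \code{"PR"}).
#' @param hyper a [hyper_params()] object.
#' @param x_star probe x-position; defaults to the hyperparameter value.
#' @param sigma_g noise hyperparameter the observer assumes; defaults to
#'   \code{hyper$sigma_g}.
#' @return A [gmix()] over \eqn{y^\star}.
#' @examples
#' h <- hyper_params(sigma_g = 0.03)
#' s <- generate_stimulus(h, w = 1)
#' round(gmix_var(predictive("PR", s, h)))   # prior-predictive variance: 16
#' @export
predictive <- function(model_id = c("PR", "MLR", "MAPR", "BR", "BRsigma"),
                       stim = NULL, hyper = hyper_params(),
                       x_star = hyper$x_star, sigma_g = hyper$sigma_g) {
  model_id <- match.arg(model_id)
  stopifnot(inherits(hyper, "hyper_params"))
  xs2 <- x_star^2
  if (model_id == "PR") {
    return(gmix(c(hyper$c_prior, 1 - hyper$c_prior),
                c(hyper$mu_pi, -hyper$mu_pi) * xs2,
                rep(hyper$sigma_pi^2 * xs2^2 + sigma_g^2, 2)))
  }
  stopifnot(inherits(stim, "stimulus"))
  if (model_id == "MLR") {
    ls <- likelihood_stats(stim, sigma_g)
    return(gmix(1, ls$w_ml * xs2, sigma_g^2))
  }
  if (model_id == "MAPR") {
    post <- posterior_w(stim, hyper, sigma_g)
    w_map <- as.numeric(map_estimate(post))
    return(gmix(1, w_map * xs2, sigma_g^2))
  }
  if (model_id == "BRsigma")
    sigma_g <- max(estimate_sigma_g(stim), SIGMA_G_FLOOR)
  post <- posterior_w(stim, hyper, sigma_g)
  g <- post$mixture
  gmix(g$weights, g$means * xs2, g$vars * xs2^2 + sigma_g^2)
}
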