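#' One-dimensional Gaussian mixture
#'
#' The universal distribution carrier of the package: priors over the quadratic
#' parameter \eqn{w}, posteriors over \eqn{w}, posterior-predictive
#' distributions over the probe value \eqn{y^\star}, and response
#' distributions over \eqn{r} are all finite mixtures of one-dimensional
#' normals \deqn{p(z) = \sum_k \pi_k \, N(z; m_k, v_k).}
#'
#' Weights are stored normalised; normalisation is carried out in log space so
#' that mixtures built from extremely unbalanced component evidences (small
#' generative noise) do not underflow.
#'
#' @param weights numeric vector of non-negative component weights (will be
#'   normalised to sum to one).
#' @param means numeric vector of component means.
#' @param vars numeric vector of strictly positive component variances.
#' @return An object of class \code{"gmix"}: a list with elements
#'   \code{weights}, \code{means}, \code{vars}.
#' @examples
#' g <- gmix(c(0.5, 0.5), c(-4, 4), c(1, 1))
#' gmix_mean(g)
#' gmix_var(g)
#' @export
gmix <- function(weights, means, vars) {
  weights <- as.numeric(weights)
  means <- as.numeric(means)
  vars <- as.numeric(vars)
  if (length(weights) != length(means) || length(means) != length(vars))
    stop("weights, means and vars must have equal length")
  if (length(weights) < 1L) stop("a mixture needs at least one component")
  if (any(!is.finite(weights)) || any(weights < 0))
    stop("weights must be finite and non-negative")
  if (any(!is.finite(means))) stop("means must be finite")
  if (any(!is.finite(vars)) || any(vars <= 0))
    stop("variances must be finite and strictly positive")
  s <- sum(weights)
  if (s <= 0) stop("at least one weight must be positive")
  structure(list(weights = weights / s, means = means, vars = vars),
            class = "gmix")
}

#' Build a mixture from log-weights
#'
#' Normalises unnormalised log-weights with the log-sum-exp trick; used
#' internally wherever component weights come from likelihood evaluations that
#' can underflow.
#'
#' @param log_weights unnormalised log component weights.
#' @param means,vars as in [gmix()].
#' @return A \code{"gmix"} object.
#' @keywords internal
#' @export
gmix_from_log_weights <- function(log_weights, means, vars) {
  m <- max(log_weights)
  w <- exp(log_weights - m)
  gmix(w, means, vars)
}

#' @export
print.gmix <- function(x, ...) {
  cat(sprintf("Gaussian mixture with %d component(s)\n", length(x$weights)))
  print(data.frame(weight = x$weights, mean = x$means, var = x$vars),
        row.names = FALSE)
  cat(sprintf("mean = %.6g, variance = %.6g\n", gmix_mean(x), gmix_var(x)))
  invisible(x)
}

#' Mixture density, distribution function and random generation
#'
#' @param x,q numeric vector of evaluation points.
#' @param g a [gmix()] object.
#' @param log logical; return log density?
#' @return \code{dgmix} the density, \code{pgmix} the CDF, \code{rgmix} a
#'   vector of \code{n} draws.
#' @export
dgmix <- function(x, g, log = FALSE) {
  stopifnot(inherits(g, "gmix"))
  k <- length(g$weights)
  # log-space accumulation: stable when component weights/densities underflow
  lp <- vapply(seq_len(k), function(i) {
    log(g$weights[i]) + stats::dnorm(x, g$means[i], sqrt(g$vars[i]), log = TRUE)
  }, numeric(length(x)))
  lp <- matrix(lp, nrow = length(x))
  m <- apply(lp, 1L, max)
  out <- m + log(rowSums(exp(lp - m)))
  out[!is.finite(m)] <- -Inf
  if (log) out else exp(out)
}

#' @rdname dgmix
#' @export
pgmix <- function(q, g) {
  stopifnot(inherits(g, "gmix"))
  out <- numeric(length(q))
  for (i in seq_along(g$weights))
    out <- out + g$weights[i] * stats::pnorm(q, g$means[i], sqrt(g$vars[i]))
  out
}

#' @rdname dgmix
#' @param n number of draws.
#' @export
rgmix <- function(n, g) {
  stopifnot(inherits(g, "gmix"))
  comp <- sample.int(length(g$weights), n, replace = TRUE, prob = g$weights)
  stats::rnorm(n, g$means[comp], sqrt(g$vars[comp]))
}

#' Analytic moments of a Gaussian mixture
#'
#' The mean is \eqn{\sum_k \pi_k m_k}; the variance is the law-of-total-variance
#' form \eqn{\sum_k \pi_k (v_k + m_k^2) - (\sum_k \pi_k m_k)^2}.
#'
#' @param g a [gmix()] object.
#' @return A single numeric value.
#' @export
gmix_mean <- function(g) {
  stopifnot(inherits(g, "gmix"))
  sum(g$weights * g$means)
}

#' @rdname gmix_mean
#' @export
gmix_var <- function(g) {
  stopifnot(inherits(g, "gmix"))
  mu <- sum(g$weights * g$means)
  sum(g$weights * (g$vars + g$means^2)) - mu^2
}

#' Convolve a mixture with zero-mean Gaussian noise
#'
#' Closed-form convolution: every component variance increases by
#' \code{sigma^2}; weights and means are untouched. \code{sigma = 0} is the
#' identity.
#'
#' @param g a [gmix()] object.
#' @param sigma standard deviation of the added independent Gaussian noise
#'   (non-negative).
#' @return A \code{"gmix"} object.
#' @export
gmix_convolve <- function(g, sigma) {
  stopifnot(inherits(g, "gmix"))
  if (!is.finite(sigma) || sigma < 0) stop("sigma must be non-negative")
  if (sigma == 0) return(g)
  gmix(g$weights, g$means, g$vars + sigma^2)
}

#' Serialise a mixture to / from a JSON record
#'
#' Small cache-friendly record holding weights, means and variances at full
#' double precision.
#'
#' @param g a [gmix()] object.
#' @param txt a JSON string produced by \code{gmix_to_json}.
#' @return \code{gmix_to_json} a JSON string; \code{gmix_from_json} a
#'   \code{"gmix"} object.
#' @export
gmix_to_json <- function(g) {
  stopifnot(inherits(g, "gmix"))
  jsonlite::toJSON(list(weights = g$weights, means = g$means, vars = g$vars),
                   digits = I(17))
}

#' @rdname gmix_to_json
#' @export
gmix_from_json <- function(txt) {
  rec <- jsonlite::fromJSON(txt)
  gmix(rec$weights, rec$means, rec$vars)
}
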