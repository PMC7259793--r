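#' Four-dot stimulus
#'
#' One trial's stimulus: four points \eqn{(x_i, y_i)} generated from the
#' parabola \eqn{y = w x^2} plus Gaussian generative noise.
#'
#' @param x strictly increasing numeric vector of four x-coordinates.
#' @param y numeric vector of four y-coordinates.
#' @param w_true generating quadratic parameter.
#' @param j stimulus index within its condition.
#' @param sigma_g_label nominal noise condition the stimulus belongs to.
#' @return An object of class \code{"stimulus"}.
#' @export
stimulus <- function(x, y, w_true = NA_real_, j = NA_integer_,
                     sigma_g_label = NA_real_) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != 4L || length(y) != 4L)
    stop("a stimulus has exactly 4 points")
  if (any(diff(x) <= 0)) stop("x must be strictly increasing")
  structure(list(x = x, y = y, w_true = w_true, j = as.integer(j),
                 sigma_g_label = sigma_g_label),
            class = "stimulus")
}

#' @export
print.stimulus <- function(x, ...) {
  cat(sprintf("4-dot stimulus (j = %s, w = %.4g, condition sigma_g = %s)\n",
              x$j, x$w_true, format(x$sigma_g_label)))
  print(data.frame(x = x$x, y = x$y), row.names = FALSE)
  invisible(x)
}

#' Draw quadratic parameters from the bimodal prior
#'
#' Samples \eqn{w \sim c\,N(\mu_\pi, \sigma_\pi^2) +
#' (1-c)\,N(-\mu_\pi, \sigma_\pi^2)}: each draw picks the upward mode with
#' probability \code{c_prior} and the downward mode otherwise.
#'
#' @param hyper a [hyper_params()] object.
#' @param n number of draws.
#' @return Numeric vector of length \code{n}.
#' @export
draw_w <- function(hyper, n = 1L) {
  stopifnot(inherits(hyper, "hyper_params"))
  up <- stats::runif(n) < hyper$c_prior
  mu <- ifelse(up, hyper$mu_pi, -hyper$mu_pi)
  stats::rnorm(n, mu, hyper$sigma_pi)
}

draw_x_design <- function(design, max_attempts_override = NULL) {
  if (is.numeric(design)) return(design)
  max_attempts <- design$max_attempts
  if (!is.null(max_attempts_override)) max_attempts <- max_attempts_override
  for (attempt in seq_len(max_attempts)) {
    x <- stats::rnorm(4L, design$means, design$sd)
    if (min(diff(sort(x))) >= design$min_spacing) return(sort(x))
  }
  stop(sprintf(
    "jittered x-design failed the %g spacing constraint in %d attempts: infeasible design",
    design$min_spacing, max_attempts))
}

#' Generate one stimulus from the generative model
#'
#' Draws \eqn{w} from the bimodal prior, takes the x-positions from the design
#' (fixed, or jittered with bounded resampling under the minimum-spacing
#' constraint), and sets \eqn{y_i = w x_i^2 + \epsilon_i} with
#' \eqn{\epsilon_i \sim N(0, \sigma_g^2)}.
#'
#' @param hyper a [hyper_params()] object.
#' @param j stimulus index recorded on the result.
#' @param w optional fixed quadratic parameter (drawn from the prior when
#'   \code{NULL}).
#' @return A [stimulus()] object.
#' @export
generate_stimulus <- function(hyper, j = NA_integer_, w = NULL) {
  stopifnot(inherits(hyper, "hyper_params"))
  if (is.null(w)) w <- draw_w(hyper)
  x <- draw_x_design(hyper$x_design)
  y <- w * x^2 + stats::rnorm(4L, 0, hyper$sigma_g)
  stimulus(x, y, w_true = w, j = j, sigma_g_label = hyper$sigma_g)
}

exp1_conditions <- function(sigma_pi = 0.1) {
  list(
    list(sigma_g_label = 0,    actual_sigma_g = 1e-5, sigma_pi = sigma_pi,
         n_unique = 1L,  n_rep = 20L, n_single = 0L, practice = TRUE),
    list(sigma_g_label = 0.03, actual_sigma_g = 0.03, sigma_pi = sigma_pi,
         n_unique = 20L, n_rep = 20L, n_single = 0L, practice = FALSE),
    list(sigma_g_label = 0.1,  actual_sigma_g = 0.1,  sigma_pi = sigma_pi,
         n_unique = 20L, n_rep = 20L, n_single = 0L, practice = FALSE),
    list(sigma_g_label = 0.4,  actual_sigma_g = 0.4,  sigma_pi = sigma_pi,
         n_unique = 20L, n_rep = 20L, n_single = 0L, practice = FALSE)
  )
}

exp2_conditions <- function(sigma_pi = 0.5) {
  list(
    list(sigma_g_label = 0,   actual_sigma_g = 1e-2, sigma_pi = sigma_pi,
         n_unique = 1L,  n_rep = 20L, n_single = 0L,   practice = TRUE),
    list(sigma_g_label = 0.1, actual_sigma_g = 0.1,  sigma_pi = sigma_pi,
         n_unique = 10L, n_rep = 10L, n_single = 100L, practice = FALSE)
  )
}

#' Generate a full synthetic experiment
#'
#' Emulates the two experimental designs of the extrapolation task.
#' \describe{
#'   \item{\code{"exp1"}}{fixed x-design \eqn{(-0.3, -0.1, 0.1, 0.3)},
#'     \eqn{\sigma_\pi = 0.1}; 20 unique stimuli per generative-noise level
#'     \eqn{\sigma_g \in \{0.03, 0.1, 0.4\}}, each scheduled 20 times (400
#'     trials per level), order randomised within level. A practice block
#'     (condition label \eqn{\sigma_g = 0}, generated at \eqn{10^{-5}}) holds
#'     20 repetitions of one near-noiseless stimulus and feeds motor-noise
#'     estimation.}
#'   \item{\code{"exp2"}}{jittered x-design, \eqn{\sigma_\pi = 0.5},
#'     \eqn{\sigma_g = 0.1}; 10 unique stimuli scheduled 10 times plus 100
#'     single-presentation stimuli (200 trials), after a 20-trial practice
#'     block generated at \eqn{\sigma_g = 10^{-2}}.}
#' }
#'
#' @param design_id \code{"exp1"} or \code{"exp2"}.
#' @param seed optional integer seed; with a fixed seed the schedule and all
#'   stimuli are reproducible.
#' @param sigma_pi override of the prior-mode standard deviation (defaults to
#'   the design's value).
#' @param include_practice generate the practice block? (default \code{TRUE}).
#' @return An object of class \code{"parextrap_experiment"}: a list with
#'   \code{design_id}, per-condition entries (hyperparameters and the unique
#'   [stimulus()] objects) and a \code{schedule} data frame with one row per
#'   scheduled trial (\code{trial}, \code{sigma_g} condition label, \code{j},
#'   \code{practice}).
#' @examples
#' ex <- generate_experiment("exp1", seed = 1)
#' table(ex$schedule$sigma_g)   # 20 practice + 400 trials per noise level
#' @export
generate_experiment <- function(design_id = c("exp1", "exp2"), seed = NULL,
                                sigma_pi = NULL, include_practice = TRUE) {
  design_id <- match.arg(design_id)
  if (!is.null(seed)) set.seed(seed)
  conds <- if (design_id == "exp1") {
    exp1_conditions(if (is.null(sigma_pi)) 0.1 else sigma_pi)
  } else {
    exp2_conditions(if (is.null(sigma_pi)) 0.5 else sigma_pi)
  }
  if (!include_practice)
    conds <- Filter(function(co) !co$practice, conds)
  x_design <- if (design_id == "exp1") c(-0.3, -0.1, 0.1, 0.3) else x_design_jitter()

  conditions <- list()
  sched <- list()
  for (co in conds) {
    hyper <- hyper_params(sigma_pi = co$sigma_pi, sigma_g = co$actual_sigma_g,
                          x_design = x_design)
    n_stim <- co$n_unique + co$n_single
    stimuli <- lapply(seq_len(n_stim), function(j) generate_stimulus(hyper, j = j))
    reps <- c(rep(seq_len(co$n_unique), each = co$n_rep),
              if (co$n_single > 0L) co$n_unique + seq_len(co$n_single))
    reps <- sample(reps)          # shuffle within the condition block
    sched[[length(sched) + 1L]] <- data.frame(
      sigma_g = co$sigma_g_label, j = reps, practice = co$practice)
    conditions[[as.character(co$sigma_g_label)]] <- list(
      sigma_g_label = co$sigma_g_label, actual_sigma_g = co$actual_sigma_g,
      sigma_pi = co$sigma_pi, hyper = hyper, stimuli = stimuli,
      practice = co$practice)
  }
  schedule <- do.call(rbind, sched)
  schedule$trial <- seq_len(nrow(schedule))
  schedule <- schedule[, c("trial", "sigma_g", "j", "practice")]
  structure(list(design_id = design_id, conditions = conditions,
                 schedule = schedule),
            class = "parextrap_experiment")
}

#' @export
print.parextrap_experiment <- function(x, ...) {
  cat(sprintf("Synthetic experiment '%s': %d scheduled trials\n",
              x$design_id, nrow(x$schedule)))
  tab <- table(x$schedule$sigma_g)
  for (nm in names(tab))
    cat(sprintf("  condition sigma_g = %s: %d trials, %d unique stimuli%s\n",
                nm, tab[[nm]], length(x$conditions[[nm]]$stimuli),
                if (x$conditions[[nm]]$practice) " (practice)" else ""))
  invisible(x)
}

#' Synthetic observer configuration
#'
#' Pairs a regression model with a decision rule and a motor-noise level.
#'
#' @param regression_model one of \code{"PR"}, \code{"MLR"}, \code{"MAPR"},
#'   \code{"BR"}, \code{"BRsigma"}.
#' @param decision_rule \code{"sampling"} (probability matching: one draw from
#'   the predictive) or \code{"loss"} (squared-loss decision theory: the
#'   predictive mean plus motor noise).
#' @param sigma_m motor-noise standard deviation; non-negative.
#' @param participant_id identifier written into simulated trial tables.
#' @return An object of class \code{"observer_config"}.
#' @export
observer_config <- function(regression_model = c("BR", "PR", "MLR", "MAPR", "BRsigma"),
                            decision_rule = c("sampling", "loss"),
                            sigma_m = 0.4, participant_id = "sim1") {
  regression_model <- match.arg(regression_model)
  decision_rule <- match.arg(decision_rule)
  if (!is.finite(sigma_m) || sigma_m < 0) stop("sigma_m must be >= 0")
  structure(list(regression_model = regression_model,
                 decision_rule = decision_rule,
                 sigma_m = sigma_m, participant_id = participant_id),
            class = "observer_config")
}

#' Simulate an observer on a synthetic experiment
#'
#' For every scheduled trial, draws one response from the configured model's
#' response distribution: under the sampling rule, a draw from the
#' motor-noise-convolved posterior predictive; under the loss rule, a draw
#' from \eqn{N(\text{predictive mean}, \sigma_m^2)} (deterministic when
#' \code{sigma_m = 0}). The observer is given the true generative
#' hyperparameters of each condition, so its predictions are fitting-free.
#'
#' @param experiment a [generate_experiment()] result.
#' @param config an [observer_config()].
#' @param seed optional integer seed.
#' @return A trial data frame (one row per scheduled trial) with columns
#'   \code{participant}, \code{sigma_pi}, \code{sigma_g} (condition label),
#'   \code{practice}, \code{j}, \code{x1..x4}, \code{y1..y4}, \code{w_true},
#'   \code{response}.
#' @export
simulate_observer <- function(experiment, config, seed = NULL) {
  stopifnot(inherits(experiment, "parextrap_experiment"),
            inherits(config, "observer_config"))
  if (!is.null(seed)) set.seed(seed)
  out <- vector("list", length(experiment$conditions))
  ci <- 0L
  for (cond in experiment$conditions) {
    ci <- ci + 1L
    sch <- experiment$schedule[experiment$schedule$sigma_g == cond$sigma_g_label, ]
    n_stim <- length(cond$stimuli)
    responses <- numeric(nrow(sch))
    for (jj in seq_len(n_stim)) {
      idx <- which(sch$j == jj)
      if (!length(idx)) next
      stim <- cond$stimuli[[jj]]
      pred <- predictive(config$regression_model, stim, cond$hyper)
      if (config$decision_rule == "sampling") {
        responses[idx] <- rgmix(length(idx), gmix_convolve(pred, config$sigma_m))
      } else {
        responses[idx] <- stats::rnorm(length(idx), gmix_mean(pred), config$sigma_m)
      }
    }
    xs <- t(vapply(cond$stimuli, function(s) s$x, numeric(4)))
    ys <- t(vapply(cond$stimuli, function(s) s$y, numeric(4)))
    ws <- vapply(cond$stimuli, function(s) s$w_true, numeric(1))
    out[[ci]] <- data.frame(
      participant = config$participant_id,
      sigma_pi = cond$sigma_pi, sigma_g = cond$sigma_g_label,
      practice = cond$practice, j = sch$j,
      x1 = xs[sch$j, 1], x2 = xs[sch$j, 2], x3 = xs[sch$j, 3], x4 = xs[sch$j, 4],
      y1 = ys[sch$j, 1], y2 = ys[sch$j, 2], y3 = ys[sch$j, 3], y4 = ys[sch$j, 4],
      w_true = ws[sch$j], response = responses)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Group a trial table into per-stimulus response sets
#'
#' @param trials a trial data frame as produced by [simulate_observer()] or
#'   [read_trials()].
#' @return A data frame with one row per (participant, condition, stimulus),
#'   holding the response list-column \code{responses} and the stimulus
#'   coordinates.
#' @export
response_sets <- function(trials) {
  key <- interaction(trials$participant, trials$sigma_pi, trials$sigma_g,
                     trials$j, drop = TRUE)
  rows <- split(seq_len(nrow(trials)), key)
  out <- lapply(rows, function(idx) {
    first <- trials[idx[1L], ]
    data.frame(participant = first$participant, sigma_pi = first$sigma_pi,
               sigma_g = first$sigma_g,
               practice = if ("practice" %in% names(first)) first$practice else FALSE,
               j = first$j,
               x1 = first$x1, x2 = first$x2, x3 = first$x3, x4 = first$x4,
               y1 = first$y1, y2 = first$y2, y3 = first$y3, y4 = first$y4,
               w_true = first$w_true, n_responses = length(idx),
               responses = I(list(trials$response[idx])))
  })
  res <- do.call(rbind, out)
  res <- res[order(res$participant, res$sigma_pi, res$sigma_g, res$j), ]
  rownames(res) <- NULL
  res
}

stimulus_from_row <- function(row) {
  stimulus(c(row$x1, row$x2, row$x3, row$x4),
           c(row$y1, row$y2, row$y3, row$y4),
           w_true = row$w_true, j = row$j, sigma_g_label = row$sigma_g)
}
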