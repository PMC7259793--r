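#' Dominant mode of a response set
#'
#' The sign (upward/downward parabola) holding strictly more than half of the
#' responses; an exact split has no dominant mode. Responses at exactly 0
#' count as positive.
#'
#' @param responses non-empty numeric vector.
#' @return \code{"+"}, \code{"-"} or \code{"none"}.
#' @export
dominant_mode_of_responses <- function(responses) {
  r <- as.numeric(responses)
  if (!length(r)) stop("responses must be non-empty")
  n_pos <- sum(r >= 0)
  if (n_pos > length(r) / 2) "+"
  else if (length(r) - n_pos > length(r) / 2) "-"
  else "none"
}

#' Dominant mode of a model's response distribution
#'
#' The sign of the component set carrying more than half of the probability
#' mass (single-component models: the sign of the mean). An exact half-half
#' split — the symmetric-prior null model on any stimulus — breaks
#' deterministically to \code{"+"} with attribute \code{tie = TRUE}.
#'
#' Because all likelihood-based models share the likelihood term and the
#' prior is symmetric, the maximum-likelihood sign decides the dominant mode
#' for every one of them, so they always agree on a stimulus.
#'
#' @param dist a [response_distribution()] result or bare [gmix()].
#' @return \code{"+"} or \code{"-"} (possibly with a \code{tie} attribute).
#' @export
dominant_mode_of_model <- function(dist) {
  g <- if (inherits(dist, "response_dist")) dist$mixture else dist
  stopifnot(inherits(g, "gmix"))
  if (length(g$weights) == 1L)
    return(if (g$means >= 0) "+" else "-")
  mass_pos <- sum(g$weights[g$means >= 0])
  if (abs(mass_pos - 0.5) <= 1e-12) {
    out <- "+"
    attr(out, "tie") <- TRUE
    return(out)
  }
  if (mass_pos > 0.5) "+" else "-"
}

#' Restrict a response distribution to one mode
#'
#' Removes the inferior mode of a bimodal distribution and renormalises the
#' remaining probability mass to one: only the components whose mean carries
#' the requested sign are kept, with weights rescaled. Unimodal distributions
#' pass through unchanged, and the operation is idempotent. Density ratios
#' between points under the retained components are unchanged.
#'
#' @param dist a [response_distribution()] result or bare [gmix()].
#' @param sign \code{"+"} or \code{"-"}.
#' @return Same class as the input.
#' @export
truncate_and_renormalize <- function(dist, sign = c("+", "-")) {
  sign <- match.arg(sign)
  g <- if (inherits(dist, "response_dist")) dist$mixture else dist
  stopifnot(inherits(g, "gmix"))
  if (length(g$weights) > 1L) {
    keep <- if (sign == "+") g$means >= 0 else g$means < 0
    if (any(keep) && !all(keep))
      g <- gmix(g$weights[keep], g$means[keep], g$vars[keep])
  }
  if (inherits(dist, "response_dist")) {
    dist$mixture <- g
    dist
  } else g
}

#' Build the dominant-mode-conditioned (unimodal) dataset
#'
#' For each stimulus, keeps the dominant-mode responses if and only if the
#' responses' dominant mode agrees with the models' dominant mode (taken from
#' the full Bayesian regression predictive, which the symmetric prior makes
#' common to all likelihood-based models). Stimuli with no dominant response
#' mode (an exact split), and stimuli where responses and models disagree on
#' the mode, are dropped with the reason recorded. Within a kept stimulus,
#' only the responses in the dominant mode are retained.
#'
#' @param trials trial data frame; practice rows are excluded.
#' @param mu_pi,c_prior,x_star generative hyperparameters.
#' @return An object of class \code{"unimodal_dataset"}: list with
#'   \describe{
#'     \item{\code{sets}}{one row per (participant, condition, stimulus):
#'       dominant response sign, model sign, \code{retained}, a
#'       \code{retention_reason} in \{kept, response_model_mode_mismatch,
#'       no_dominant_mode\}, the retained responses (list column), and
#'       counts.}
#'     \item{\code{retention}}{per-condition retained-trial fraction
#'       (retained responses over all responses, averaged over
#'       participants).}
#'     \item{\code{trials}}{the retained responses in the trial-table
#'       schema, ready for [compare_all()].}
#'     \item{\code{signs}}{the conditioning map consumed by
#'       [unimodal_compare()].}
#'   }
#' @export
build_unimodal_dataset <- function(trials, mu_pi = 1, c_prior = 0.5,
                                   x_star = 2) {
  if ("practice" %in% names(trials)) trials <- trials[!trials$practice, ]
  rsets <- response_sets(trials)
  rows <- list()
  signs <- list()
  kept_trials <- list()
  for (i in seq_len(nrow(rsets))) {
    row <- rsets[i, ]
    r <- row$responses[[1L]]
    resp_sign <- dominant_mode_of_responses(r)
    hyper <- condition_hyper(row$sigma_pi, row$sigma_g, mu_pi, c_prior, x_star)
    stim <- stimulus_from_row(row)
    model_sign <- as.character(dominant_mode_of_model(
      predictive("BR", stim, hyper)))
    if (resp_sign == "none") {
      retained <- FALSE; reason <- "no_dominant_mode"
    } else if (resp_sign != model_sign) {
      retained <- FALSE; reason <- "response_model_mode_mismatch"
    } else {
      retained <- TRUE; reason <- "kept"
    }
    kept <- if (retained) {
      if (resp_sign == "+") r[r >= 0] else r[r < 0]
    } else numeric(0)
    key <- paste(row$participant, row$sigma_pi, row$sigma_g, sep = "|")
    if (is.null(signs[[key]])) signs[[key]] <- list()
    signs[[key]][[as.character(row$j)]] <-
      if (retained) model_sign else NA_character_
    rows[[length(rows) + 1L]] <- data.frame(
      participant = row$participant, sigma_pi = row$sigma_pi,
      sigma_g = row$sigma_g, j = row$j,
      response_sign = resp_sign, model_sign = model_sign,
      retained = retained, retention_reason = reason,
      n_retained = length(kept), n_total = length(r),
      retained_responses = I(list(kept)))
    if (retained && length(kept)) {
      kt <- trials[rep(i, length(kept)), 0]  # placeholder frame sizing
      kt <- data.frame(
        participant = row$participant, sigma_pi = row$sigma_pi,
        sigma_g = row$sigma_g, practice = FALSE, j = row$j,
        x1 = row$x1, x2 = row$x2, x3 = row$x3, x4 = row$x4,
        y1 = row$y1, y2 = row$y2, y3 = row$y3, y4 = row$y4,
        w_true = row$w_true, response = kept)
      kept_trials[[length(kept_trials) + 1L]] <- kt
    }
  }
  sets <- do.call(rbind, rows)
  # per-condition retained fraction: responses kept / responses seen,
  # computed per participant, then averaged over participants
  ckey <- interaction(sets$participant, sets$sigma_pi, sets$sigma_g, drop = TRUE)
  per_part <- do.call(rbind, lapply(split(sets, ckey), function(d) {
    data.frame(participant = d$participant[1], sigma_pi = d$sigma_pi[1],
               sigma_g = d$sigma_g[1],
               fraction = sum(d$n_retained) / sum(d$n_total))
  }))
  gkey <- interaction(per_part$sigma_pi, per_part$sigma_g, drop = TRUE)
  retention <- do.call(rbind, lapply(split(per_part, gkey), function(d) {
    data.frame(sigma_pi = d$sigma_pi[1], sigma_g = d$sigma_g[1],
               retention_fraction = mean(d$fraction),
               n_participants = nrow(d))
  }))
  rownames(retention) <- NULL
  out_trials <- if (length(kept_trials)) do.call(rbind, kept_trials) else NULL
  if (!is.null(out_trials)) rownames(out_trials) <- NULL
  structure(list(sets = sets, retention = retention,
                 trials = out_trials, signs = signs),
            class = "unimodal_dataset")
}

#' @export
print.unimodal_dataset <- function(x, ...) {
  cat("Dominant-mode-conditioned dataset\n")
  cat("Retention fractions (trials kept, averaged over participants):\n")
  print(x$retention, row.names = FALSE)
  tab <- table(x$sets$retention_reason)
  cat("Stimulus dispositions:", paste(names(tab), tab, sep = " = ",
                                      collapse = ", "), "\n")
  invisible(x)
}

#' Model comparison on the dominant-mode-conditioned dataset
#'
#' Composes [build_unimodal_dataset()] with [compare_all()]: every retained
#' response is scored under each model's response distribution truncated to
#' the shared dominant mode and renormalised, so that no retained response
#' can fall under a removed mode. Everything else — models, rules, baseline,
#' the fitting-free contract — is unchanged from the full comparison.
#'
#' @inheritParams compare_all
#' @return A list with the \code{"model_comparison"} result (element
#'   \code{comparison}) and the underlying \code{"unimodal_dataset"}
#'   (element \code{dataset}).
#' @export
unimodal_compare <- function(trials, sigma_m,
                             models = MODEL_IDS, rules = DECISION_RULES,
                             baseline_model = "BR", baseline_rule = "sampling",
                             mu_pi = 1, c_prior = 0.5, x_star = 2) {
  ds <- build_unimodal_dataset(trials, mu_pi, c_prior, x_star)
  if (is.null(ds$trials)) stop("conditioning retained no responses")
  cmp <- compare_all(ds$trials, sigma_m, models, rules,
                     baseline_model, baseline_rule,
                     mu_pi, c_prior, x_star, unimodal_signs = ds$signs)
  list(comparison = cmp, dataset = ds)
}
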