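#' Log-density floor
#'
#' Per-response log densities are floored at the double-precision underflow
#' bound so that a single outlying response cannot drive a model's summed log
#' likelihood to \code{-Inf}; the number of floored responses is reported.
#' @keywords internal
LOG_DENSITY_FLOOR <- -746

MODEL_IDS <- c("PR", "MLR", "MAPR", "BR", "BRsigma")
DECISION_RULES <- c("sampling", "loss")

floored_log_density <- function(g, responses) {
  ld <- dgmix(responses, g, log = TRUE)
  n_floored <- sum(ld < LOG_DENSITY_FLOOR)
  ld[ld < LOG_DENSITY_FLOOR] <- LOG_DENSITY_FLOOR
  structure(sum(ld), n_floored = n_floored)
}

#' Summed log likelihood of response data under per-stimulus distributions
#'
#' \deqn{L_M = \sum_j \sum_{r \in R_j} \log p(r | D_j, x^\star, M)}
#' summed over stimuli and over the repeated responses to each, with the
#' motor-noise-convolved response distribution supplying the density.
#'
#' @param dists named list (keyed by stimulus index) of
#'   [response_distribution()] results or bare [gmix()] objects.
#' @param responses named list (same keys) of numeric response vectors, or a
#'   [response_sets()] data frame whose \code{j} column supplies the keys.
#' @return The summed log likelihood (numeric scalar) with attribute
#'   \code{n_floored}, the number of responses whose log density hit the
#'   underflow floor. Empty data give 0.
#' @export
log_likelihood <- function(dists, responses) {
  if (is.data.frame(responses)) {
    keys <- as.character(responses$j)
    responses <- stats::setNames(responses$responses, keys)
  }
  total <- 0
  n_floored <- 0L
  for (key in names(responses)) {
    r <- responses[[key]]
    if (!length(r)) next
    d <- dists[[key]]
    if (is.null(d)) stop(sprintf("no response distribution for stimulus '%s'", key))
    g <- if (inherits(d, "response_dist")) d$mixture else d
    s <- floored_log_density(g, r)
    total <- total + as.numeric(s)
    n_floored <- n_floored + attr(s, "n_floored")
  }
  structure(total, n_floored = n_floored)
}

condition_hyper <- function(sigma_pi, sigma_g, mu_pi = 1, c_prior = 0.5,
                            x_star = 2) {
  hyper_params(mu_pi = mu_pi, sigma_pi = sigma_pi, c_prior = c_prior,
               sigma_g = sigma_g, x_star = x_star)
}

score_model_rule <- function(rsets_cond, hyper, sigma_m, model_id, rule,
                             unimodal_sign = NULL) {
  total <- 0
  n_resp <- 0L
  n_floored <- 0L
  for (i in seq_len(nrow(rsets_cond))) {
    row <- rsets_cond[i, ]
    stim <- stimulus_from_row(row)
    pred <- predictive(model_id, stim, hyper)
    rd <- response_distribution(pred, sigma_m, rule, model_id = model_id)
    if (!is.null(unimodal_sign)) {
      sgn <- unimodal_sign[[as.character(row$j)]]
      if (is.null(sgn) || is.na(sgn)) next   # stimulus dropped by conditioning
      rd <- truncate_and_renormalize(rd, sgn)
    }
    r <- row$responses[[1L]]
    s <- floored_log_density(rd$mixture, r)
    total <- total + as.numeric(s)
    n_resp <- n_resp + length(r)
    n_floored <- n_floored + attr(s, "n_floored")
  }
  list(log_lik = total, n_responses = n_resp, n_floored = n_floored)
}

#' Fitting-free model comparison by summed log likelihood
#'
#' Scores every regression-model x decision-rule pair on each participant's
#' responses, condition by condition. All model predictions are fixed
#' functions of the stimulus and the true generative hyperparameters — no
#' hyperparameter is adjusted to the data, so summed log likelihoods are
#' directly comparable across models (the comparison coincides with BIC).
#' Only the motor noise \eqn{\sigma_m} is participant-specific, estimated
#' separately from noise-free practice responses.
#'
#' @param trials trial data frame ([simulate_observer()] / [read_trials()]
#'   schema); practice rows are excluded automatically.
#' @param sigma_m motor noise: a single value, or a named vector keyed by
#'   participant.
#' @param models regression models to score.
#' @param rules decision rules to score.
#' @param baseline_model,baseline_rule the reference pair for log-likelihood
#'   deltas (default: Bayesian regression with sampling).
#' @param mu_pi,c_prior,x_star generative hyperparameters shared by all
#'   conditions.
#' @param unimodal_signs optional conditioning map (built by
#'   [build_unimodal_dataset()]); used internally for the unimodal comparison.
#' @return An object of class \code{"model_comparison"}: list with
#'   \code{per_participant} (participant x condition x model x rule log
#'   likelihoods and deltas), \code{group} (across-participant mean and SEM of
#'   the deltas per condition x model x rule) and the baseline label.
#' @export
compare_all <- function(trials, sigma_m,
                        models = MODEL_IDS, rules = DECISION_RULES,
                        baseline_model = "BR", baseline_rule = "sampling",
                        mu_pi = 1, c_prior = 0.5, x_star = 2,
                        unimodal_signs = NULL) {
  if ("practice" %in% names(trials)) trials <- trials[!trials$practice, ]
  rsets <- response_sets(trials)
  participants <- unique(rsets$participant)
  conds <- unique(rsets[, c("sigma_pi", "sigma_g")])
  rows <- list()
  for (k in participants) {
    sm <- if (length(sigma_m) > 1L || !is.null(names(sigma_m))) {
      if (is.null(names(sigma_m)) || !(as.character(k) %in% names(sigma_m)))
        stop(sprintf("no sigma_m supplied for participant '%s'", k))
      sigma_m[[as.character(k)]]
    } else sigma_m
    for (ci in seq_len(nrow(conds))) {
      sp <- conds$sigma_pi[ci]; sg <- conds$sigma_g[ci]
      rc <- rsets[rsets$participant == k & rsets$sigma_pi == sp &
                    rsets$sigma_g == sg, ]
      if (!nrow(rc)) next
      hyper <- condition_hyper(sp, sg, mu_pi, c_prior, x_star)
      usign <- if (is.null(unimodal_signs)) NULL else
        unimodal_signs[[paste(k, sp, sg, sep = "|")]]
      for (m in models) for (ru in rules) {
        sc <- score_model_rule(rc, hyper, sm, m, ru, unimodal_sign = usign)
        rows[[length(rows) + 1L]] <- data.frame(
          participant = k, sigma_pi = sp, sigma_g = sg, model = m, rule = ru,
          log_lik = sc$log_lik, n_responses = sc$n_responses,
          n_floored = sc$n_floored)
      }
    }
  }
  pp <- do.call(rbind, rows)
  # deltas vs the baseline pair, within participant x condition
  pp$delta <- NA_real_
  key <- interaction(pp$participant, pp$sigma_pi, pp$sigma_g, drop = TRUE)
  for (kk in levels(key)) {
    idx <- which(key == kk)
    base <- idx[pp$model[idx] == baseline_model & pp$rule[idx] == baseline_rule]
    if (length(base) != 1L)
      stop("baseline model/rule not scored for every participant x condition")
    pp$delta[idx] <- pp$log_lik[idx] - pp$log_lik[base]
  }
  gkey <- interaction(pp$sigma_pi, pp$sigma_g, pp$model, pp$rule, drop = TRUE)
  group <- do.call(rbind, lapply(split(pp, gkey), function(d) {
    data.frame(sigma_pi = d$sigma_pi[1], sigma_g = d$sigma_g[1],
               model = d$model[1], rule = d$rule[1],
               mean_delta = mean(d$delta),
               sem_delta = if (nrow(d) > 1L)
                 stats::sd(d$delta) / sqrt(nrow(d)) else NA_real_,
               n_participants = nrow(d))
  }))
  rownames(group) <- NULL
  structure(list(per_participant = pp, group = group,
                 baseline = list(model = baseline_model, rule = baseline_rule)),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf("Model comparison (baseline: %s + %s rule)\n",
              x$baseline$model, x$baseline$rule))
  cat("Group-level log-likelihood deltas (mean +/- SEM across participants):\n")
  print(x$group, row.names = FALSE)
  invisible(x)
}

#' Bayesian random-effects model selection
#'
#' Hierarchical analysis of which fraction of the population each candidate
#' model describes: participants' model assignments follow a multinomial with
#' Dirichlet-distributed frequencies. The posterior Dirichlet parameters are
#' found by the standard variational-Bayes iteration — responsibilities
#' \deqn{g_{km} \propto \exp\left(\log E_{km} + \psi(\alpha_m) -
#'   \psi(\textstyle\sum_m \alpha_m)\right)}
#' normalised over models for each participant \eqn{k}, then
#' \eqn{\alpha_m = \alpha_0 + \sum_k g_{km}}, iterated to convergence
#' (\eqn{\psi} the digamma function). The report is the normalised Dirichlet
#' parameter \eqn{\alpha_M / \sum \alpha}, the expected model frequency for a
#' randomly selected participant.
#'
#' @param log_evidence numeric matrix, participants x models, of per-subject
#'   log model evidences (here: summed log likelihoods, the setting being
#'   fitting-free).
#' @param alpha0 symmetric Dirichlet prior parameter (default 1,
#'   uninformative).
#' @param tol convergence threshold on \eqn{\max_m |\Delta\alpha_m|}.
#' @param max_iter iteration cap; exceeding it is an error.
#' @return An object of class \code{"random_effects"}: list with
#'   \code{alpha}, \code{alpha_normalized} (= expected model frequencies),
#'   \code{responsibilities}, \code{iterations}.
#' @examples
#' le <- matrix(c(0, -50, 0, -50), nrow = 2, byrow = TRUE,
#'              dimnames = list(NULL, c("A", "B")))
#' random_effects(le)$alpha_normalized
#' @export
random_effects <- function(log_evidence, alpha0 = 1, tol = 1e-6,
                           max_iter = 10000L) {
  log_evidence <- as.matrix(log_evidence)
  if (any(!is.finite(log_evidence))) stop("log evidences must be finite")
  K <- nrow(log_evidence); M <- ncol(log_evidence)
  if (K < 1L || M < 2L) stop("need >= 1 participant and >= 2 models")
  alpha <- rep(alpha0, M)
  g <- matrix(NA_real_, K, M)
  for (it in seq_len(max_iter)) {
    lg <- sweep(log_evidence, 2L, digamma(alpha) - digamma(sum(alpha)), "+")
    lg <- lg - apply(lg, 1L, max)
    g <- exp(lg) / rowSums(exp(lg))
    alpha_new <- alpha0 + colSums(g)
    if (max(abs(alpha_new - alpha)) < tol) {
      alpha <- alpha_new
      mods <- colnames(log_evidence)
      names(alpha) <- mods
      return(structure(list(alpha = alpha,
                            alpha_normalized = alpha / sum(alpha),
                            responsibilities = g, iterations = it),
                       class = "random_effects"))
    }
    alpha <- alpha_new
  }
  stop(sprintf(
    "random-effects iteration did not converge in %d iterations (last max |dalpha| = %g)",
    max_iter, max(abs(alpha0 + colSums(g) - alpha))))
}

#' @export
print.random_effects <- function(x, ...) {
  cat(sprintf("Random-effects model selection (%d iterations)\n", x$iterations))
  cat("Expected model frequencies (normalised Dirichlet parameters):\n")
  print(round(x$alpha_normalized, 4))
  invisible(x)
}
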