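# Independent numerical oracles used across the test files. These integrate
# the generative densities directly (piecewise adaptive quadrature, Gibbs
# sampling, brute-force summation) and never call the closed-form package
# internals they are checking.

# Piecewise adaptive quadrature of f over [-R, R], subdividing around the
# supplied centers so narrow spikes are never stepped over.
piecewise_integrate <- function(f, centers, widths, R) {
  pts <- sort(unique(pmin(pmax(
    c(-R, R, rep(centers, each = 2) + c(-12, 12) * rep(widths, each = 2)),
    -R), R)))
  total <- 0
  for (i in seq_len(length(pts) - 1L)) {
    if (pts[i + 1L] - pts[i] < 1e-300) next
    total <- total + stats::integrate(f, pts[i], pts[i + 1L],
                                      rel.tol = 1e-12, abs.tol = 1e-14,
                                      subdivisions = 400L)$value
  }
  total
}

# Log of the unnormalised posterior over w: likelihood x bimodal prior.
oracle_log_joint <- function(w, stim, hyper, sigma_g) {
  lik <- vapply(w, function(wi)
    sum(stats::dnorm(stim$y, wi * stim$x^2, sigma_g, log = TRUE)), numeric(1))
  prior <- log(hyper$c_prior * stats::dnorm(w, hyper$mu_pi, hyper$sigma_pi) +
               (1 - hyper$c_prior) * stats::dnorm(w, -hyper$mu_pi, hyper$sigma_pi))
  lik + prior
}

oracle_quad_setup <- function(stim, hyper, sigma_g) {
  # independent least-squares fit of y ~ x^2 for the likelihood center/width
  fit <- stats::lm(stim$y ~ 0 + I(stim$x^2))
  w_ls <- unname(stats::coef(fit))
  s <- sigma_g / sqrt(sum(stim$x^4))
  post_w <- sqrt(1 / (1 / hyper$sigma_pi^2 + 1 / s^2))
  centers <- c(w_ls, hyper$mu_pi, -hyper$mu_pi,
               (w_ls / s^2 + hyper$mu_pi / hyper$sigma_pi^2) * post_w^2,
               (w_ls / s^2 - hyper$mu_pi / hyper$sigma_pi^2) * post_w^2)
  widths <- c(s, hyper$sigma_pi, hyper$sigma_pi, post_w, post_w)
  R <- max(abs(centers) + 15 * widths, 3)
  off <- max(oracle_log_joint(centers, stim, hyper, sigma_g))
  list(centers = centers, widths = widths, R = R, off = off)
}

# Normalised posterior density over w at the given points, by quadrature.
oracle_posterior_density <- function(w_pts, stim, hyper, sigma_g) {
  su <- oracle_quad_setup(stim, hyper, sigma_g)
  f <- function(w) exp(oracle_log_joint(w, stim, hyper, sigma_g) - su$off)
  Z <- piecewise_integrate(f, su$centers, su$widths, su$R)
  f(w_pts) / Z
}

# Posterior-predictive density at y-points by double quadrature:
# p(y) = (1/Z) \int N(y; w x*^2, pred_sd^2) exp(log joint) dw.
oracle_predictive_density <- function(y_pts, stim, hyper, sigma_g, pred_sd,
                                      x_star = hyper$x_star) {
  su <- oracle_quad_setup(stim, hyper, sigma_g)
  f0 <- function(w) exp(oracle_log_joint(w, stim, hyper, sigma_g) - su$off)
  Z <- piecewise_integrate(f0, su$centers, su$widths, su$R)
  xs2 <- x_star^2
  vapply(y_pts, function(y) {
    f <- function(w) stats::dnorm(y, w * xs2, pred_sd) * f0(w)
    piecewise_integrate(f, c(su$centers, y / xs2),
                        c(su$widths, pred_sd / xs2), su$R) / Z
  }, numeric(1))
}

# Prior-predictive density (no stimulus) by quadrature over the prior.
oracle_prior_predictive_density <- function(y_pts, hyper, sigma_g,
                                            x_star = hyper$x_star) {
  xs2 <- x_star^2
  prior_d <- function(w)
    hyper$c_prior * stats::dnorm(w, hyper$mu_pi, hyper$sigma_pi) +
    (1 - hyper$c_prior) * stats::dnorm(w, -hyper$mu_pi, hyper$sigma_pi)
  centers <- c(hyper$mu_pi, -hyper$mu_pi)
  widths <- rep(hyper$sigma_pi, 2)
  R <- max(abs(centers) + 15 * widths, 3)
  vapply(y_pts, function(y) {
    f <- function(w) stats::dnorm(y, w * xs2, sigma_g) * prior_d(w)
    piecewise_integrate(f, c(centers, y / xs2), c(widths, sigma_g / xs2), R)
  }, numeric(1))
}

# 6-sigma evaluation grid over the components of a closed-form mixture.
# (Evaluation points may come from the object under test; the oracle values
# at those points are computed independently.)
six_sigma_grid <- function(g, n_per = 13L) {
  sort(unique(as.vector(outer(seq(-6, 6, length.out = n_per),
                              sqrt(g$vars), "*") +
                          rep(g$means, each = n_per))))
}

# Independent posterior-mode oracle: root of the analytic score function
# d/dw [log likelihood + log prior], bracketed around a coarse grid argmax.
oracle_w_map <- function(stim, hyper, sigma_g) {
  score <- function(w) {
    lik <- sum(stim$x^2 * (stim$y - w * stim$x^2)) / sigma_g^2
    num <- hyper$c_prior * stats::dnorm(w, hyper$mu_pi, hyper$sigma_pi) *
      (-(w - hyper$mu_pi) / hyper$sigma_pi^2) +
      (1 - hyper$c_prior) * stats::dnorm(w, -hyper$mu_pi, hyper$sigma_pi) *
      (-(w + hyper$mu_pi) / hyper$sigma_pi^2)
    den <- hyper$c_prior * stats::dnorm(w, hyper$mu_pi, hyper$sigma_pi) +
      (1 - hyper$c_prior) * stats::dnorm(w, -hyper$mu_pi, hyper$sigma_pi)
    lik + num / den
  }
  grid <- seq(-4, 4, length.out = 8001)
  lj <- oracle_log_joint(grid, stim, hyper, sigma_g)
  w0 <- grid[which.max(lj)]
  h <- 0.02
  while (score(w0 - h) * score(w0 + h) > 0 && h > 1e-10) h <- h / 2
  stats::uniroot(score, c(w0 - h, w0 + h), tol = 1e-13)$root
}

# Gibbs sampler for the hierarchical random-effects model: population model
# frequencies r ~ Dirichlet(alpha0), per-subject assignment m_k ~ Cat(r),
# subject evidence exp(logE[k, m]). Returns the posterior mean of the
# normalised Dirichlet parameter (alpha0 + counts) / sum.
gibbs_random_effects <- function(log_evidence, alpha0 = 1, n_iter = 20000L,
                                 burn = 2000L) {
  K <- nrow(log_evidence); M <- ncol(log_evidence)
  r <- rep(1 / M, M)
  acc <- numeric(M)
  kept <- 0L
  for (it in seq_len(n_iter)) {
    counts <- numeric(M)
    for (k in seq_len(K)) {
      lp <- log(r) + log_evidence[k, ]
      p <- exp(lp - max(lp)); p <- p / sum(p)
      m_k <- sample.int(M, 1L, prob = p)
      counts[m_k] <- counts[m_k] + 1
    }
    gam <- stats::rgamma(M, shape = alpha0 + counts, rate = 1)
    r <- gam / sum(gam)
    if (it > burn) {
      acc <- acc + (alpha0 + counts) / (M * alpha0 + K)
      kept <- kept + 1L
    }
  }
  acc / kept
}

# Hand-build a one-condition experiment object (bypasses the designs) so
# observers can be simulated with arbitrary repetition counts.
make_experiment <- function(stimuli, n_rep, hyper, label = hyper$sigma_g) {
  schedule <- data.frame(
    trial = seq_len(length(stimuli) * n_rep),
    sigma_g = label,
    j = rep(seq_along(stimuli), each = n_rep),
    practice = FALSE)
  structure(list(
    design_id = "custom",
    conditions = stats::setNames(list(list(
      sigma_g_label = label, actual_sigma_g = hyper$sigma_g,
      sigma_pi = hyper$sigma_pi, hyper = hyper, stimuli = stimuli,
      practice = FALSE)), as.character(label)),
    schedule = schedule), class = "parextrap_experiment")
}

# Total-variation distance between two density functions on a shared grid.
tv_distance <- function(d1, d2, grid) {
  0.5 * sum(abs(d1 - d2)) * mean(diff(grid))
}
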