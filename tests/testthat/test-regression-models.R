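main_design <- c(-0.3, -0.1, 0.1, 0.3)

test_that("likelihood statistics have their closed-form values", {
  h <- hyper_params(sigma_g = 0.03)
  s <- stimulus(main_design, 2 * main_design^2, w_true = 2)
  ls <- likelihood_stats(s, 0.03)
  expect_equal(ls$sum_x4, 0.0164)          # direct summation of the design
  expect_equal(ls$w_ml, 2)                 # noiseless data recover w exactly
  expect_equal(likelihood_stats(s, 5)$w_ml, 2)  # ... for any sigma_g
  s_neg <- stimulus(s$x, -s$y)
  expect_equal(likelihood_stats(s_neg, 0.03)$w_ml, -2)
  expect_error(likelihood_stats(s, 0), "sigma_g")
  expect_error(stimulus(c(0, 0, 0, 0), rep(1, 4)), "strictly increasing")
})

test_that("posterior over w matches the quadrature oracle on random stimuli", {
  set.seed(21)
  for (i in 1:12) {
    sg <- runif(1, 0.02, 0.6)
    h <- hyper_params(sigma_g = sg)
    s <- generate_stimulus(h)
    post <- posterior_w(s, h)
    pts <- six_sigma_grid(post$mixture)
    expect_lt(max(abs(dgmix(pts, post$mixture) -
                        oracle_posterior_density(pts, s, h, sg))), 1e-6)
  }
})

test_that("an uninformative likelihood returns the prior; a symmetric stimulus splits the weights", {
  h <- hyper_params(sigma_g = 1e3)
  s <- stimulus(main_design, c(0.09, 0.01, 0.01, 0.09), w_true = 1)
  post <- posterior_w(s, h)
  grid <- seq(-2, 2, length.out = 4001)
  tv <- tv_distance(dgmix(grid, post$mixture), dgmix(grid, prior_w(h)), grid)
  expect_lt(tv, 1e-3)

  # w_ml = 0: the two modes are equally likely
  h2 <- hyper_params(sigma_g = 0.1)
  s0 <- stimulus(main_design, c(0.05, -0.05, 0.05, -0.05))
  expect_equal(likelihood_stats(s0, 0.1)$w_ml, 0)
  expect_equal(posterior_w(s0, h2)$mixture$weights, c(0.5, 0.5))
})

test_that("MAP estimation matches a dense-grid argmax and breaks ties upward", {
  set.seed(22)
  for (i in 1:10) {
    g <- gmix(runif(2), rnorm(2, c(-1, 1), 0.3), runif(2, 0.001, 0.05))
    w_map <- as.numeric(map_estimate(g))
    grid <- seq(min(g$means) - 1, max(g$means) + 1, length.out = 400001)
    w_grid <- grid[which.max(dgmix(grid, g))]
    expect_lt(abs(w_map - w_grid), 1e-5)
  }
  # dominant component
  g <- gmix(c(0.999, 0.001), c(1, -1), c(0.01, 0.01))
  expect_equal(as.numeric(map_estimate(g)), 1, tolerance = 1e-4)
  # exact symmetry: deterministic positive tie-break, flagged
  h <- hyper_params(sigma_g = 0.1)
  s0 <- stimulus(main_design, c(0.05, -0.05, 0.05, -0.05))
  w_tie <- map_estimate(posterior_w(s0, h))
  expect_true(isTRUE(attr(w_tie, "tie")))
  expect_gt(as.numeric(w_tie), 0)
})

test_that("trial-by-trial noise estimate equals the ML residual formula and is biased downward", {
  s_clean <- stimulus(main_design, 3 * main_design^2)
  expect_equal(estimate_sigma_g(s_clean), 0)
  # perturbed parabola, brute-force residual arithmetic
  delta <- 0.1
  y <- c(0.09, 0.01, 0.01, 0.09) + c(delta, -delta, -delta, delta)
  s <- stimulus(main_design, y)
  w_star <- sum(y * main_design^2) / sum(main_design^4)
  expect_equal(estimate_sigma_g(s),
               sqrt(mean((y - w_star * main_design^2)^2)), tolerance = 1e-12)
  # ML downward bias at n = 1e4 simulated stimuli
  set.seed(23)
  h <- hyper_params(sigma_g = 0.1)
  s2hat <- vapply(1:1e4, function(i) estimate_sigma_g(generate_stimulus(h))^2,
                  numeric(1))
  expect_lt(mean(s2hat), 0.1^2)
})

test_that("predictive distributions have their stated closed forms and match quadrature", {
  set.seed(24)
  h <- hyper_params(sigma_g = 0.03)
  s <- generate_stimulus(h)
  # prior-predictive variance at the probe rounds to 16
  expect_equal(round(gmix_var(predictive("PR", s, h))), 16)
  # probe at the vertex: every model predicts 0
  for (m in c("PR", "MLR", "MAPR", "BR", "BRsigma"))
    expect_equal(gmix_mean(predictive(m, s, h, x_star = 0)), 0,
                 tolerance = 1e-12)
  # quadrature agreement for the stimulus-using models, across noise levels
  for (sg in c(0.03, 0.1, 0.4)) {
    hh <- hyper_params(sigma_g = sg)
    ss <- generate_stimulus(hh)
    for (m in c("BR", "BRsigma")) {
      sg_used <- if (m == "BR") sg else max(estimate_sigma_g(ss), 1e-6)
      pred <- predictive(m, ss, hh)
      pts <- six_sigma_grid(pred)
      expect_lt(max(abs(dgmix(pts, pred) -
                          oracle_predictive_density(pts, ss, hh, sg_used,
                                                    pred_sd = sg_used))),
                1e-6)
    }
  }
})

test_that("modality of the Bayesian predictive tracks the generative noise", {
  h_low <- hyper_params(sigma_g = 0.03)
  h_high <- hyper_params(sigma_g = 0.4)
  clean <- stimulus(main_design, 1.0 * main_design^2, w_true = 1)
  near_sym <- stimulus(main_design, 0.02 * main_design^2, w_true = 0.02)
  p_low <- predictive("BR", clean, h_low)
  expect_gt(max(p_low$weights), 0.999)            # effectively unimodal
  p_high <- predictive("BR", near_sym, h_high)
  expect_true(all(p_high$weights > 0.2))          # two comparable modes
  expect_gt(abs(diff(p_high$means)), 4)           # well separated
})

test_that("B-R interpolates between MAP-R and P-R as the noise varies", {
  main <- stimulus(main_design, 1.02 * main_design^2, w_true = 1.02)
  # clean data, small noise: B-R mean approaches MAP-R mean
  h_small <- hyper_params(sigma_g = 1e-4)
  expect_equal(gmix_mean(predictive("BR", main, h_small)),
               gmix_mean(predictive("MAPR", main, h_small)), tolerance = 1e-6)
  # huge noise: B-R predictive converges to P-R in total variation
  h_big <- hyper_params(sigma_g = 1e3)
  grid <- seq(-3e3, 3e3, length.out = 40001)
  tv <- tv_distance(dgmix(grid, predictive("BR", main, h_big)),
                    dgmix(grid, predictive("PR", main, h_big)), grid)
  expect_lt(tv, 1e-3)
})

test_that("ML-R ignores the prior; every model is sign-equivariant", {
  h1 <- hyper_params(mu_pi = 1, sigma_pi = 0.1, c_prior = 0.5, sigma_g = 0.1)
  h2 <- hyper_params(mu_pi = 3, sigma_pi = 0.7, c_prior = 0.9, sigma_g = 0.1)
  s <- stimulus(main_design, c(0.1, 0.0, 0.02, 0.07))
  expect_identical(predictive("MLR", s, h1), predictive("MLR", s, h2))

  s_neg <- stimulus(s$x, -s$y)
  for (m in c("PR", "MLR", "MAPR", "BR", "BRsigma")) {
    p <- predictive(m, s, h1)
    pn <- predictive(m, s_neg, h1)
    pts <- six_sigma_grid(p)
    expect_equal(dgmix(pts, p), dgmix(-pts, pn), tolerance = 1e-9,
                 label = sprintf("mirrored predictive (%s)", m))
  }
})

test_that("mixture variance obeys the equal-variance two-mode decomposition identity", {
  set.seed(25)
  for (i in 1:50) {
    cc <- runif(1)
    mu <- sort(rnorm(2, 0, 4))
    v <- runif(1, 0.01, 2)
    g <- gmix(c(cc, 1 - cc), c(mu[2], mu[1]), c(v, v))
    expect_equal(gmix_var(g), v + cc * (1 - cc) * (mu[2] - mu[1])^2,
                 tolerance = 1e-12)
  }
})
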