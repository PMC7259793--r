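test_that("summed log likelihood matches brute-force summation and handles edge cases", {
  # empty data: empty sum
  expect_equal(as.numeric(log_likelihood(list(), list())), 0)
  # single response at the mean of a unit-variance Gaussian: log(1/sqrt(2*pi))
  g <- gmix(1, 2.5, 1)
  expect_equal(as.numeric(log_likelihood(list(`1` = g), list(`1` = 2.5))),
               log(1 / sqrt(2 * pi)), tolerance = 1e-12)
  # random data: independent naive double loop
  set.seed(41)
  dists <- list(`1` = gmix(c(0.4, 0.6), c(-4, 4), c(1, 2)),
                `2` = gmix(1, 0.5, 0.3))
  resp <- list(`1` = rnorm(7, 0, 4), `2` = rnorm(5))
  naive <- 0
  for (key in names(resp)) for (r in resp[[key]]) {
    d <- dists[[key]]
    naive <- naive + log(sum(d$weights * dnorm(r, d$means, sqrt(d$vars))))
  }
  expect_equal(as.numeric(log_likelihood(dists, resp)), naive,
               tolerance = 1e-10)
  # an absurd outlier hits the floor instead of -Inf
  far <- log_likelihood(list(`1` = gmix(1, 0, 1e-4)), list(`1` = 1e3))
  expect_true(is.finite(as.numeric(far)))
  expect_equal(attr(far, "n_floored"), 1L)
})

test_that("log-likelihood ranking is invariant to a joint shift of responses and means", {
  set.seed(42)
  r <- rnorm(20, 1, 2)
  models <- list(a = gmix(1, 1, 4), b = gmix(1, 0, 1),
                 c = gmix(c(0.5, 0.5), c(-2, 2), c(1, 1)))
  shift <- 11.3
  ll <- vapply(models, function(g)
    as.numeric(log_likelihood(list(`1` = g), list(`1` = r))), numeric(1))
  ll_shift <- vapply(models, function(g) {
    g2 <- gmix(g$weights, g$means + shift, g$vars)
    as.numeric(log_likelihood(list(`1` = g2), list(`1` = r + shift)))
  }, numeric(1))
  expect_equal(order(ll), order(ll_shift))
  expect_equal(ll, ll_shift, tolerance = 1e-9)
})

test_that("random-effects analysis returns symmetric, dominant and pairwise-equal solutions", {
  # all models identical: uniform normalised alpha
  le <- matrix(0, nrow = 7, ncol = 3, dimnames = list(NULL, c("A", "B", "C")))
  re <- random_effects(le)
  expect_equal(unname(re$alpha_normalized), rep(1 / 3, 3), tolerance = 1e-8)
  expect_equal(sum(re$alpha_normalized), 1, tolerance = 1e-10)
  # one model 50 log-units ahead for all seven participants: hard assignment,
  # so alpha = (alpha0 + 7, alpha0) and the normalised weight is exactly 8/9
  le2 <- cbind(A = rep(0, 7), B = rep(-50, 7))
  re2 <- random_effects(le2)
  expect_equal(re2$alpha_normalized[["A"]], 8 / 9, tolerance = 1e-6)
  # single participant, two equal models
  re3 <- random_effects(cbind(A = 0, B = 0))
  expect_equal(unname(re3$alpha_normalized), c(0.5, 0.5), tolerance = 1e-8)
  # permutation equivariance
  set.seed(43)
  le4 <- matrix(rnorm(21, sd = 3), 7, 3, dimnames = list(NULL, c("A", "B", "C")))
  re4 <- random_effects(le4)
  re4p <- random_effects(le4[, c(3, 1, 2)])
  expect_equal(unname(re4p$alpha_normalized),
               unname(re4$alpha_normalized[c(3, 1, 2)]), tolerance = 1e-6)
  expect_error(random_effects(cbind(A = c(0, NA), B = c(0, 0))), "finite")
  expect_error(random_effects(matrix(0, 3, 1)), ">= 2 models")
})

test_that("random-effects variational solution agrees with a Gibbs-sampler oracle", {
  set.seed(44)
  le <- cbind(A = c(0, 0, 0, -3, 1, 0.5, 0),
              B = c(-2, -1, -4, 0, -1, -2, -3))
  vb <- random_effects(le)$alpha_normalized
  gibbs <- gibbs_random_effects(le, n_iter = 20000L)
  expect_lt(max(abs(vb - gibbs)), 0.02)
})

test_that("full comparison reports zero baseline deltas and per-participant bookkeeping", {
  set.seed(45)
  h <- hyper_params(sigma_g = 0.1)
  stims <- lapply(1:4, function(j) generate_stimulus(h, j = j))
  ex <- make_experiment(stims, n_rep = 10L, hyper = h)
  trials <- rbind(
    simulate_observer(ex, observer_config("BR", "sampling", 0.4, "p1")),
    simulate_observer(ex, observer_config("BR", "sampling", 0.3, "p2")))
  cmp <- compare_all(trials, sigma_m = c(p1 = 0.4, p2 = 0.3))
  pp <- cmp$per_participant
  base <- pp[pp$model == "BR" & pp$rule == "sampling", ]
  expect_true(all(base$delta == 0))
  expect_true(all(pp$n_responses == 40))
  expect_equal(nrow(cmp$group), 10)      # 5 models x 2 rules, one condition
  expect_error(compare_all(trials, sigma_m = c(p1 = 0.4)), "p2")
})

test_that("data simulated from a model are best explained by that model", {
  set.seed(46)
  h <- hyper_params(sigma_g = 0.1)
  stims <- lapply(1:10, function(j) generate_stimulus(h, j = j))
  ex <- make_experiment(stims, n_rep = 20L, hyper = h)
  score_top <- function(gen_model) {
    tr <- simulate_observer(ex, observer_config(gen_model, "sampling", 0.4, "s"))
    cmp <- compare_all(tr, 0.4, rules = "sampling")
    pp <- cmp$per_participant
    pp$model[which.max(pp$log_lik)]
  }
  expect_equal(score_top("BR"), "BR")
  # P-R data: the point-estimate models score far below both P-R and B-R
  tr_pr <- simulate_observer(ex, observer_config("PR", "sampling", 0.4, "s"))
  cmp <- compare_all(tr_pr, 0.4, rules = "sampling")
  pp <- cmp$per_participant
  ll <- setNames(pp$log_lik, pp$model)
  expect_gt(min(ll["PR"], ll["BR"]) - max(ll["MLR"], ll["MAPR"]), 100)
})
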