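test_that("dominant response mode needs a strict majority", {
  expect_equal(dominant_mode_of_responses(c(rep(4, 11), rep(-4, 9))), "+")
  expect_equal(dominant_mode_of_responses(rep(-2, 5)), "-")
  expect_equal(dominant_mode_of_responses(c(rep(1, 10), rep(-1, 10))), "none")
  expect_error(dominant_mode_of_responses(numeric(0)), "non-empty")
})

test_that("model dominant mode follows the probability mass, tie-breaking upward", {
  g <- gmix(c(0.8, 0.2), c(4, -4), c(1, 1))
  expect_equal(dominant_mode_of_model(g), "+")
  expect_equal(dominant_mode_of_model(gmix(1, -2, 1)), "-")
  sym <- gmix(c(0.5, 0.5), c(4, -4), c(1, 1))
  mode <- dominant_mode_of_model(sym)
  expect_equal(as.character(mode), "+")
  expect_true(isTRUE(attr(mode, "tie")))
})

test_that("likelihood-sharing models agree on the dominant mode of any stimulus", {
  set.seed(61)
  for (sg in c(0.03, 0.1, 0.4)) {
    h <- hyper_params(sigma_g = sg)
    for (i in 1:10) {
      s <- generate_stimulus(h)
      signs <- vapply(c("MLR", "MAPR", "BR", "BRsigma"), function(m)
        as.character(dominant_mode_of_model(predictive(m, s, h))),
        character(1))
      expect_equal(length(unique(signs)), 1L)
    }
  }
})

test_that("mode truncation renormalises, preserves density ratios and is idempotent", {
  g <- gmix(c(0.7, 0.3), c(4, -4), c(0.5, 0.5))
  tg <- truncate_and_renormalize(g, "+")
  expect_length(tg$weights, 1L)
  expect_equal(tg$weights, 1)
  expect_equal(tg$means, 4)
  # density ratio between retained points unchanged
  pts <- c(3.2, 4.9)
  expect_equal(dgmix(pts[1], tg) / dgmix(pts[2], tg),
               (g$weights[1] * dnorm(pts[1], 4, sqrt(0.5))) /
                 (g$weights[1] * dnorm(pts[2], 4, sqrt(0.5))),
               tolerance = 1e-12)
  # idempotent; unimodal distributions pass through untouched
  expect_identical(truncate_and_renormalize(tg, "+"), tg)
  mono <- gmix(1, -3, 1)
  expect_identical(truncate_and_renormalize(mono, "+"), mono)
  # response_dist wrapper preserved
  rd <- response_distribution(g, 0.3, "sampling")
  rd_t <- truncate_and_renormalize(rd, "-")
  expect_s3_class(rd_t, "response_dist")
  expect_equal(rd_t$mixture$means, -4)
})

test_that("conditioning keeps dominant-mode responses only when models agree", {
  set.seed(62)
  h <- hyper_params(sigma_g = 0.03)
  # three clean stimuli: responses all in the model's mode -> retention 1
  stims <- lapply(1:3, function(j) generate_stimulus(h, j = j))
  ex <- make_experiment(stims, n_rep = 20L, hyper = h)
  tr <- simulate_observer(ex, observer_config("MAPR", "loss", 0.01, "s"))
  ds <- build_unimodal_dataset(tr)
  expect_equal(ds$retention$retention_fraction, 1)
  expect_true(all(ds$sets$retention_reason == "kept"))

  # a hand-built exact split is omitted with its reason recorded
  s1 <- stims[[1]]
  tr_tie <- data.frame(participant = "t", sigma_pi = 0.1, sigma_g = 0.03,
                       practice = FALSE, j = 1L,
                       x1 = s1$x[1], x2 = s1$x[2], x3 = s1$x[3], x4 = s1$x[4],
                       y1 = s1$y[1], y2 = s1$y[2], y3 = s1$y[3], y4 = s1$y[4],
                       w_true = s1$w_true,
                       response = c(rep(4, 10), rep(-4, 10)))
  ds_tie <- build_unimodal_dataset(tr_tie)
  expect_equal(ds_tie$sets$retention_reason, "no_dominant_mode")
  expect_equal(ds_tie$retention$retention_fraction, 0)

  # responses opposing the model's mode are disregarded entirely
  w_sign <- if (s1$w_true > 0) 1 else -1
  tr_opp <- tr_tie
  tr_opp$response <- rep(-4 * w_sign, 20)
  ds_opp <- build_unimodal_dataset(tr_opp)
  expect_equal(ds_opp$sets$retention_reason, "response_model_mode_mismatch")
})

test_that("retention of a Bayesian observer weakly decreases with generative noise", {
  set.seed(63)
  fractions <- vapply(c(0.03, 0.1, 0.4), function(sg) {
    h <- hyper_params(sigma_g = sg)
    stims <- lapply(1:20, function(j) generate_stimulus(h, j = j))
    ex <- make_experiment(stims, n_rep = 20L, hyper = h, label = sg)
    tr <- simulate_observer(ex, observer_config("BR", "sampling", 0.4, "s"))
    build_unimodal_dataset(tr)$retention$retention_fraction
  }, numeric(1))
  expect_true(all(fractions >= 0 & fractions <= 1))
  expect_gt(fractions[1], 0.9)          # near-total retention at low noise
  expect_true(all(diff(fractions) <= 0.05))  # weakly decreasing (MC slack)
})

test_that("after conditioning no retained response falls under a removed mode", {
  set.seed(64)
  h <- hyper_params(sigma_g = 0.4)
  stims <- lapply(1:10, function(j) generate_stimulus(h, j = j))
  ex <- make_experiment(stims, n_rep = 20L, hyper = h)
  tr <- simulate_observer(ex, observer_config("BR", "sampling", 0.4, "s"))
  uc <- unimodal_compare(tr, 0.4, rules = "sampling")
  # the formerly bimodal models keep positive density on every retained
  # response once truncated to the shared mode (ML-R can still underflow on
  # extreme maximum-likelihood excursions; that is not a removed-mode effect)
  pp_bimodal <- subset(uc$comparison$per_participant,
                       model %in% c("PR", "BR", "BRsigma"))
  expect_true(all(pp_bimodal$n_floored == 0))
  # composition contract: deltas of the baseline are zero, all models scored
  pp <- uc$comparison$per_participant
  expect_true(all(pp$delta[pp$model == "BR" & pp$rule == "sampling"] == 0))
  expect_setequal(unique(pp$model), c("PR", "MLR", "MAPR", "BR", "BRsigma"))
})
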