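# Utility functions, the logistic rule, likelihoods and simulation.

test_that("power expected utility matches hand arithmetic and rejects bad exponents", {
  expect_equal(expected_utility(lottery(1.0, 5), 1), 5)
  expect_equal(expected_utility(lottery(0.5, 20), 1), 10)
  expect_equal(expected_utility(lottery(0.75, 50), 0.55),
               0.75 * exp(0.55 * log(50)), tolerance = 1e-12)
  expect_equal(round(expected_utility(lottery(0.75, 50), 0.55), 2), 6.45)
  expect_error(expected_utility(lottery(0.5, 20), 0), "positive")
  expect_error(expected_utility(lottery(0.5, 20), -1), "positive")
  # strictly increasing in amount and in win probability
  expect_gt(expected_utility(lottery(0.5, 21), 0.7), expected_utility(lottery(0.5, 20), 0.7))
  expect_gt(expected_utility(lottery(0.6, 20), 0.7), expected_utility(lottery(0.5, 20), 0.7))
})

test_that("social-weighted utility interpolates between self and friend", {
  self <- lottery(0.5, 20)
  friend <- lottery(1.0, 5)
  p0 <- social_params(0.8, 1, 0, 0.6)
  expect_equal(opposite_pair_utility(self, friend, p0),
               expected_utility(self, 0.8))
  p1 <- social_params(0.8, 1, 1, 0.6)
  expect_equal(opposite_pair_utility(self, friend, p1),
               expected_utility(friend, 0.6))
  # symmetric mixing at w = 0.5 with equal exponents
  ph <- social_params(1, 1, 0.5, 1)
  expect_equal(opposite_pair_utility(self, friend, ph), 7.5)
  expect_equal(opposite_pair_utility(friend, self, ph), 7.5)
  expect_error(social_params(0.8, 1, 1.2, 0.6), "0, 1")
})

test_that("logistic choice rule is calibrated and numerically stable", {
  expect_equal(p_choose_risky(3, 3, 5), 0.5)
  expect_equal(p_choose_risky(2, 7, 0), 0.5)
  expect_equal(p_choose_risky(0, 1, 2), 1 / (1 + exp(-2)), tolerance = 1e-12)
  # monotone in the utility advantage
  expect_gt(p_choose_risky(5, 7, 1), p_choose_risky(5, 6, 1))
  # stable far beyond overflow territory
  expect_equal(p_choose_risky(0, 1e4, 1), 1)
  expect_equal(p_choose_risky(1e4, 0, 1), 0)
  expect_true(is.finite(stats::plogis(-1e4, log.p = TRUE)))
  expect_error(p_choose_risky(1, 2, -0.5), "non-negative")
})

test_that("prospect-theory weighting preserves endpoints and nests expected utility", {
  expect_equal(pt_expected_utility(lottery(0.1, 10), 1, 1),
               expected_utility(lottery(0.1, 10), 1), tolerance = 1e-12)
  for (g in c(0.4, 0.61, 1, 1.3)) {
    expect_equal(pt_expected_utility(lottery(1, 10), 1, g), 10, tolerance = 1e-9)
  }
  # hand evaluation of the weighting function at gamma = 0.61
  g <- 0.61
  pw <- 0.1^g / (0.1^g + 0.9^g)^(1 / g)
  expect_equal(pt_expected_utility(lottery(0.1, 10), 1, g), pw * 10,
               tolerance = 1e-12)
  expect_error(pt_expected_utility(lottery(0.1, 10), 1, -0.2), "positive")
  expect_error(pt_params(1, 1.6, 1), "1.5")
})

test_that("log-likelihood equals a brute-force per-trial oracle", {
  for (model in c("original", "revised", "prospect")) {
    for (s in 1:34) {
      rec <- random_records(35, seed = s)
      params <- random_params(model, seed = 100 * s)
      expect_equal(log_likelihood(rec, model, params),
                   oracle_loglik(rec, model, params),
                   tolerance = 1e-10)
    }
  }
})

test_that("log-likelihood limits: chance floor and deterministic ceiling", {
  rec <- random_records(35, seed = 5)
  expect_equal(log_likelihood(rec, "original", original_params(0.7, 0)),
               35 * log(0.5), tolerance = 1e-12)
  # perfectly utility-consistent choices approach zero at large beta (trials
  # exactly at the indifference point stay 50/50 and are left out)
  set <- build_choice_set("Baseline", seed = 6)
  set$chose_risky <- deterministic_choices(set, 1)
  thr <- indifference_alpha(set$p_win, set$amount, set$safe_amount)
  untied <- set[is.na(thr) | abs(thr - 1) > 1e-9, ]
  ll <- log_likelihood(untied, "original", original_params(1, 40))
  expect_gt(ll, -1e-3)
  expect_lte(ll, 0)
  # always a log-probability
  expect_lte(log_likelihood(rec, "original", original_params(1.3, 2)), 0)
})

test_that("revised model with w = 0 reproduces the original model exactly", {
  for (s in 1:10) {
    rec <- random_records(35, seed = s)
    alpha <- 0.2 + s / 10
    beta <- s / 3
    expect_equal(log_likelihood(rec, "revised", social_params(alpha, beta, 0, 1.7)),
                 log_likelihood(rec, "original", original_params(alpha, beta)),
                 tolerance = 1e-15)
  }
})

test_that("noise-free choices are monotone in the risk exponent", {
  # once an agent with exponent a1 takes a risky option, every agent with
  # a2 > a1 takes it too (threshold rule); with raw-dollar utilities the
  # choice *probability* at finite noise is not monotone on dominated trials,
  # so the property is asserted at the deterministic level
  set <- build_choice_set("Baseline", seed = 9)
  withr::with_seed(21, {
    for (i in 1:50) {
      a1 <- stats::runif(1, 0.05, 3)
      a2 <- a1 + stats::runif(1, 1e-6, 2)
      c1 <- deterministic_choices(set, a1)
      c2 <- deterministic_choices(set, a2)
      expect_true(all(c2 >= c1))
    }
  })
})

test_that("choice simulation is seeded and hits its limiting regimes", {
  set <- build_choice_set("Baseline", seed = 4)
  p <- original_params(0.9, 3)
  expect_identical(simulate_choices(p, "original", set, seed = 42),
                   simulate_choices(p, "original", set, seed = 42))
  # chance regime
  flat <- original_params(1, 0)
  rate <- mean(vapply(1:40, function(s) {
    mean(simulate_choices(flat, "original", set, seed = s)$chose_risky)
  }, numeric(1)))
  expect_equal(rate, 0.5, tolerance = 0.05)
  # deterministic regime: risky iff EV > 5 at alpha = 1 (EV ties stay random)
  det <- simulate_choices(original_params(1, 500), "original", set, seed = 1)
  ev <- set$p_win * set$amount
  not_tied <- abs(ev - 5) > 1e-9
  expect_identical(det$chose_risky[not_tied], (ev > 5)[not_tied])
})
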