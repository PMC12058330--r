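# Maximum-likelihood fitting, chance AIC, and model-based exclusions.

test_that("original-model fit recovers known generating parameters", {
  set <- build_choice_set("Baseline", seed = 1)
  alphas <- vapply(1:8, function(s) {
    rec <- simulate_choices(original_params(0.7, 5), "original", set, seed = s)
    fit_original(rec)$alpha
  }, numeric(1))
  expect_lt(abs(mean(alphas) - 0.7), 0.1)
  expect_true(all(abs(alphas - 0.7) < 0.4))
})

test_that("fit results satisfy the AIC identity and carry diagnostics", {
  set <- build_choice_set("Baseline", seed = 2)
  rec <- simulate_choices(original_params(0.55, 3), "original", set, seed = 3)
  f <- fit_original(rec, "P01", "Baseline")
  expect_equal(f$aic, 2 * f$k - 2 * f$loglik)
  expect_equal(f$k, 2L)
  expect_lte(f$loglik, 0)
  expect_true(f$converged)
  rec_o <- simulate_choices(social_params(0.8, 3, 0.3, 0.6), "revised",
                            build_choice_set("Opposite", seed = 4), seed = 5)
  fr <- fit_revised(rec_o, 0.6, "P01", "Opposite")
  expect_equal(fr$k, 3L)
  expect_equal(fr$aic, 2 * 3 - 2 * fr$loglik)
  expect_equal(fr$alpha_friend, 0.6)
})

test_that("degenerate record sets are flagged rather than crashing", {
  set <- build_choice_set("Baseline", seed = 7)
  all_safe <- set
  all_safe$chose_risky <- FALSE
  f <- fit_original(all_safe)
  expect_lt(f$alpha, 0.3) # no risky information pins alpha low
  expect_true(f$boundary)
  expect_error(fit_original(set[1:5, ]), "at least 10")
  expect_error(fit_revised(simulate_choices(original_params(1, 1), "original",
                                            set, 1), alpha_friend = Inf),
               "finite")
})

test_that("multi-start optimization is stable at moderate noise", {
  set <- build_choice_set("Baseline", seed = 8)
  agree <- vapply(1:10, function(s) {
    rec <- simulate_choices(original_params(0.6 + s / 20, 2 + s / 2), "original",
                            set, seed = s)
    f <- fit_original(rec)
    f$n_starts_agreeing / 12
  }, numeric(1))
  expect_gte(mean(agree), 0.9)
})

test_that("revised-model fit recovers the friend weight and nests the original", {
  # the friend exponent is set well apart from the self exponent; when the
  # two nearly coincide the self/friend utility-difference vectors are close
  # to collinear over the 35-trial grid and the weight is barely identified
  set <- build_choice_set("Opposite", seed = 10)
  ws <- vapply(1:8, function(s) {
    rec <- simulate_choices(social_params(1.0, 5, 0.4, 1.6), "revised", set, seed = s)
    fit_revised(rec, 1.6)$w
  }, numeric(1))
  expect_lt(abs(mean(ws) - 0.4), 0.1)

  # w = 0 data: the revised fit never falls below the nested original fit,
  # and gains at most the one-extra-parameter overfitting allowance
  rec0 <- simulate_choices(social_params(0.8, 4, 0, 0.6), "revised", set, seed = 30)
  fr <- fit_revised(rec0, 0.6)
  fo <- fit_original(rec0)
  expect_gte(fr$loglik, fo$loglik - 1e-6)
  expect_lt(fr$loglik - fo$loglik, 1.5)

  # smooth response to a perturbed friend constant
  rec <- simulate_choices(social_params(1.0, 5, 0.4, 1.6), "revised", set, seed = 2)
  w_lo <- fit_revised(rec, 1.5)$w
  w_hi <- fit_revised(rec, 1.7)$w
  expect_true(is.finite(w_lo) && is.finite(w_hi))
  expect_lt(abs(w_lo - w_hi), 0.35)
})

test_that("friend-exponent constant is recovered from predicted-friend choices", {
  set <- build_choice_set("PredictedFriend", seed = 11)
  ests <- vapply(1:6, function(s) {
    rec <- simulate_choices(original_params(0.5, 4), "original", set, seed = 40 + s)
    as.numeric(estimate_alpha_friend(rec))
  }, numeric(1))
  expect_lt(abs(mean(ests) - 0.5), 0.1)
  rec <- simulate_choices(original_params(0.5, 4), "original", set, seed = 41)
  af <- estimate_alpha_friend(rec, "P07")
  expect_identical(attr(af, "fit")$condition, "PredictedFriend")
})

test_that("chance AIC follows its closed form", {
  expect_equal(chance_aic(35, 2), 4 + 70 * log(2), tolerance = 1e-12)
  expect_equal(round(chance_aic(35, 2), 2), 52.52)
  expect_equal(round(chance_aic(35, 3), 2), 54.52)
  expect_equal(chance_aic(1, 0), 2 * log(2), tolerance = 1e-12)
  expect_error(chance_aic(0, 2))
})

test_that("coin-flip behavior is flagged by the chance-AIC rule", {
  set <- build_choice_set("Baseline", seed = 12)
  flagged <- vapply(1:20, function(s) {
    rec <- simulate_choices(original_params(1, 0), "original", set, seed = 60 + s)
    f <- fit_original(rec, "P01", "Baseline")
    apply_exclusions(f)$excluded
  }, logical(1))
  # the fitted model beats the zero-parameter chance AIC only if its
  # likelihood improves on chance by more than its own penalty
  expect_gte(mean(flagged), 0.7)
})

test_that("exclusion rules fire on the documented bounds", {
  base <- tibble::tibble(
    participant_id = c("P1", "P2", "P3", "P4", "P5"),
    condition = c("Baseline", "Opposite", "Opposite", "Identical", "Opposite"),
    model = c("original", "revised", "revised", "original", "revised"),
    alpha = c(3.40, 2.10, 1.0, 3.20, 0.8),
    w = c(NA, 0.4, 1e-7, NA, 0.3),
    k = c(2, 3, 3, 2, 3),
    n_trials = 35,
    aic = c(20, 30, 30, 30, chance_aic(35, 0) + 1)
  )
  flags <- apply_exclusions(base)
  expect_equal(flags$excluded, c(TRUE, TRUE, TRUE, FALSE, TRUE))
  expect_match(flags$reasons[1], "alpha_bound")
  expect_match(flags$reasons[2], "alpha_bound")
  expect_match(flags$reasons[3], "w_bound")
  expect_match(flags$reasons[5], "aic_chance")
  expect_identical(flags$reasons[4], "")
  # excluded is true exactly when a reason is recorded
  expect_equal(flags$excluded, nzchar(flags$reasons))
  # boundary case: 3.32 itself is not "exceeding"
  at_bound <- base[1, ]
  at_bound$alpha <- 3.32
  expect_false(apply_exclusions(at_bound)$excluded)
  expect_error(apply_exclusions(dplyr::mutate(base, condition = "Nope")),
               "unknown condition")
  # full-sample sensitivity mode: thresholds can be relaxed via the config
  loose <- exclusion_config(alpha_max_baseline_identical = 99,
                            alpha_max_opposite = 99, w_min = 1e-300,
                            aic_vs_chance = FALSE)
  expect_false(any(apply_exclusions(base, loose)$excluded))
})
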