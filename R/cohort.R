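# Synthetic dyad-cohort generator: seeded agents and full trial-level
# datasets with the statistical structure the downstream analysis assumes.

#' Synthetic cohort configuration
#'
#' Defaults emulate the study population: 64 dyads (128 participants) aged
#' 12.0-22.8 years, pairs within 1.39 years of each other (mean gap ~0.46),
#' baseline risk exponents Normal(0.55, 0.23) truncated to (0.05, 2),
#' inverse noise LogNormal(log 3, 0.5), a friend-outcome weight declining
#' linearly with age, and an additive risk-exponent shift in the Opposite
#' context of +0.14 at the youngest age tapering linearly to zero by age
#' 15.1. Observation shifts in the Identical context reproduce the reported
#' condition means; observation has no effect on the friend weight.
#'
#' @param n_dyads Number of dyads (2 participants each).
#' @param age_range Age range in years.
#' @param age_gap_mean,age_gap_sd,age_gap_max Distribution of the within-dyad
#'   age difference (truncated normal, years).
#' @param alpha_mean,alpha_sd Baseline risk-exponent distribution.
#' @param alpha_trunc Truncation bounds for the baseline exponent.
#' @param beta_meanlog,beta_sdlog Log-normal inverse-noise parameters.
#' @param w_intercept,w_age_slope,w_noise_sd Linear-in-age friend-weight
#'   model `w = clamp(intercept + slope * age + noise, 0, 1)`; the default
#'   slope is negative (about -0.019 per year, giving means near 0.45 at age
#'   12 and 0.24 at age 22.8).
#' @param opposite_shift_young Additive exponent shift in Opposite-context
#'   conditions at the youngest age.
#' @param opposite_shift_end_age Age at which the Opposite shift has tapered
#'   to zero.
#' @param belief_noise_sd SD of the noise between the friend's true exponent
#'   and the participant's belief about it.
#' @param condition_alpha_shifts Named additive exponent shifts for the
#'   non-Opposite conditions (relative to baseline).
#' @param seed Default seed used by [generate_cohort()].
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_dyads = 64,
                          age_range = c(12.0, 22.8),
                          age_gap_mean = 0.46,
                          age_gap_sd = 0.33,
                          age_gap_max = 1.39,
                          alpha_mean = 0.55,
                          alpha_sd = 0.23,
                          alpha_trunc = c(0.05, 2),
                          beta_meanlog = log(3),
                          beta_sdlog = 0.5,
                          w_intercept = 0.67,
                          w_age_slope = -0.019,
                          w_noise_sd = 0.10,
                          opposite_shift_young = 0.14,
                          opposite_shift_end_age = 15.1,
                          belief_noise_sd = 0.10,
                          condition_alpha_shifts = c(Identical = 0.04,
                                                     UnobservedIdentical = 0.39,
                                                     ObservedIdentical = 0.49),
                          seed = 1L) {
  stopifnot(n_dyads >= 1, length(age_range) == 2, age_range[1] < age_range[2],
            alpha_sd > 0, alpha_trunc[1] > 0, alpha_trunc[1] < alpha_trunc[2],
            age_gap_max > 0, w_noise_sd >= 0, belief_noise_sd >= 0)
  structure(as.list(environment()), class = "cohort_config")
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("Synthetic dyad-cohort configuration\n")
  cat(sprintf("  %d dyads (%d participants), ages %.1f-%.1f\n",
              x$n_dyads, 2 * x$n_dyads, x$age_range[1], x$age_range[2]))
  cat(sprintf("  alpha ~ N(%.2f, %.2f) truncated to (%.2f, %.2f); beta ~ LogN(%.2f, %.2f)\n",
              x$alpha_mean, x$alpha_sd, x$alpha_trunc[1], x$alpha_trunc[2],
              x$beta_meanlog, x$beta_sdlog))
  cat(sprintf("  w = clamp(%.2f %+.3f * age + N(0, %.2f), 0, 1)\n",
              x$w_intercept, x$w_age_slope, x$w_noise_sd))
  cat(sprintf("  Opposite shift: %+.2f at age %.1f tapering to 0 by %.1f\n",
              x$opposite_shift_young, x$age_range[1], x$opposite_shift_end_age))
  invisible(x)
}

rnorm_trunc <- function(n, mean, sd, lower, upper) {
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need)) {
    draw <- stats::rnorm(length(need), mean, sd)
    ok <- draw > lower & draw < upper
    out[need[ok]] <- draw[ok]
    need <- need[!ok]
  }
  out
}

# Opposite-context additive exponent shift at a given age: linear taper from
# `shift` at the youngest age to 0 at `end_age`.
opposite_shift <- function(age, config) {
  a0 <- config$age_range[1]
  end <- config$opposite_shift_end_age
  config$opposite_shift_young * pmax(0, (end - age) / (end - a0))
}

#' Generate a synthetic dyad cohort
#'
#' Draws agents in age-matched pairs with true generative parameters:
#' baseline risk exponent, inverse noise, an age-declining friend-outcome
#' weight, a noisy belief about the friend's exponent, and per-condition
#' additive exponent shifts. Fully seeded.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed (defaults to `config$seed`).
#' @return A tibble of agents (one row each) with the configuration attached
#'   as attribute `"config"`. Columns include `participant_id`, `dyad_id`,
#'   `age`, `true_alpha`, `true_beta`, `true_w`, `true_alpha_friend_belief`,
#'   and one `shift_<condition>` column per condition.
#' @export
generate_cohort <- function(config = cohort_config(), seed = config$seed) {
  stopifnot(inherits(config, "cohort_config"))
  state <- local_rng_state(seed)
  on.exit(restore_rng_state(state), add = TRUE)
  n_d <- config$n_dyads
  lo <- config$age_range[1]
  hi <- config$age_range[2]

  age1 <- stats::runif(n_d, lo, hi)
  gap <- rnorm_trunc(n_d, config$age_gap_mean, config$age_gap_sd, 0.01, config$age_gap_max)
  age2 <- pmin(pmax(age1 + sample(c(-1, 1), n_d, replace = TRUE) * gap, lo), hi)

  n <- 2 * n_d
  agents <- tibble::tibble(
    participant_id = sprintf("P%03d", seq_len(n)),
    dyad_id = sprintf("D%02d", rep(seq_len(n_d), each = 2)),
    age = as.numeric(rbind(age1, age2)),
    true_alpha = rnorm_trunc(n, config$alpha_mean, config$alpha_sd,
                             config$alpha_trunc[1], config$alpha_trunc[2]),
    true_beta = stats::rlnorm(n, config$beta_meanlog, config$beta_sdlog)
  )
  agents$true_w <- pmin(pmax(config$w_intercept + config$w_age_slope * agents$age +
                               stats::rnorm(n, 0, config$w_noise_sd), 0), 1)
  # belief about the friend = the dyad partner's true exponent plus noise
  partner <- ifelse(seq_len(n) %% 2 == 1, seq_len(n) + 1, seq_len(n) - 1)
  agents$true_alpha_friend_belief <- pmax(
    agents$true_alpha[partner] + stats::rnorm(n, 0, config$belief_noise_sd), 0.05)

  for (cond in risk_conditions()) {
    shift <- if (is_opposite_condition(cond)) {
      opposite_shift(agents$age, config)
    } else if (cond %in% names(config$condition_alpha_shifts)) {
      rep(unname(config$condition_alpha_shifts[[cond]]), n)
    } else {
      rep(0, n)
    }
    agents[[paste0("shift_", cond)]] <- shift
  }
  attr(agents, "config") <- config
  agents
}

#' Simulate a full trial-level study dataset from a cohort
#'
#' For every agent and every condition, builds a fresh 35-trial choice set
#' (order and side assignment seeded per block) and simulates choices from
#' the generative model of that condition: the original model for Baseline /
#' Identical-context blocks (with the agent's condition shift added to the
#' exponent), the original model at the agent's belief exponent for the
#' PredictedFriend block, and the revised model (using `true_w` and the
#' belief exponent) for Opposite-context blocks.
#'
#' @param cohort A cohort from [generate_cohort()].
#' @param seed Integer seed for trial orders and choices.
#' @return A long-format tibble: `participant_id`, `dyad_id`, `age`,
#'   `condition`, `trial_index`, `p_win`, `amount`, `safe_amount`,
#'   `risky_side`, `chose_risky`.
#' @export
generate_study_dataset <- function(cohort, seed = 1L) {
  stopifnot(is.data.frame(cohort), nrow(cohort) > 0)
  config <- attr(cohort, "config")
  if (is.null(config)) stop("cohort lacks its `config` attribute; use generate_cohort()")
  state <- local_rng_state(seed)
  on.exit(restore_rng_state(state), add = TRUE)
  n_blocks <- nrow(cohort) * length(risk_conditions())
  block_seeds <- sample.int(.Machine$integer.max - 1L, 2L * n_blocks)
  b <- 0L
  out <- vector("list", n_blocks)
  for (i in seq_len(nrow(cohort))) {
    ag <- cohort[i, ]
    for (cond in risk_conditions()) {
      b <- b + 1L
      set <- build_choice_set(cond, seed = block_seeds[2L * b - 1L])
      if (cond == "PredictedFriend") {
        params <- original_params(ag$true_alpha_friend_belief, ag$true_beta)
        model <- "original"
      } else if (is_opposite_condition(cond)) {
        a <- clamp_alpha(ag$true_alpha + ag[[paste0("shift_", cond)]])
        params <- social_params(a, ag$true_beta, ag$true_w,
                                ag$true_alpha_friend_belief)
        model <- "revised"
      } else {
        a <- clamp_alpha(ag$true_alpha + ag[[paste0("shift_", cond)]])
        params <- original_params(a, ag$true_beta)
        model <- "original"
      }
      rec <- simulate_choices(params, model, set, seed = block_seeds[2L * b])
      rec$participant_id <- ag$participant_id
      rec$dyad_id <- ag$dyad_id
      rec$age <- ag$age
      out[[b]] <- rec
    }
  }
  dplyr::relocate(dplyr::bind_rows(out), "participant_id", "dyad_id", "age")
}

clamp_alpha <- function(a) pmin(pmax(a, .fit_bounds$alpha[1]), .fit_bounds$alpha[2])
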