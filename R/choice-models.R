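# Utility functions, the logistic choice rule, likelihoods and simulation for
# the original (expected-utility), revised (social-weighted) and prospect-theory
# choice models.

#' Model parameter containers
#'
#' Light validated containers for the free parameters of each choice model.
#' `original_params()` holds the risk exponent `alpha` (> 0; < 1 concave /
#' risk averse, 1 risk neutral, > 1 convex / risk seeking) and the inverse
#' decision noise `beta` (>= 0; larger means choices track expected utility
#' more deterministically). `social_params()` adds the friend-outcome weight
#' `w` in \[0, 1\] and the fixed friend exponent `alpha_friend`, a
#' per-participant constant estimated from predicted-friend choices and never
#' re-fit jointly. `pt_params()` adds the probability-weighting curvature
#' `gamma` in (0, 1.5\]; `gamma = 1` reduces the weighting to the identity so
#' the model collapses to plain expected utility.
#'
#' @param alpha Risk-preference exponent, > 0.
#' @param beta Inverse decision noise, >= 0.
#' @param w Friend-outcome weight in \[0, 1\].
#' @param alpha_friend Fixed friend risk exponent, > 0.
#' @param gamma Probability-weighting curvature in (0, 1.5].
#' @return A named list of class `risk_params`.
#' @export
original_params <- function(alpha, beta) {
  stopifnot(is.numeric(alpha), is.numeric(beta), length(alpha) == 1, length(beta) == 1)
  if (alpha <= 0) stop("`alpha` must be positive")
  if (beta < 0) stop("`beta` must be non-negative")
  structure(list(alpha = alpha, beta = beta), class = "risk_params", model = "original")
}

#' @rdname original_params
#' @export
social_params <- function(alpha, beta, w, alpha_friend) {
  stopifnot(length(w) == 1, length(alpha_friend) == 1)
  if (alpha <= 0) stop("`alpha` must be positive")
  if (beta < 0) stop("`beta` must be non-negative")
  if (w < 0 || w > 1) stop("`w` must be in [0, 1]")
  if (!is.finite(alpha_friend) || alpha_friend <= 0) stop("`alpha_friend` must be finite and positive")
  structure(list(alpha = alpha, beta = beta, w = w, alpha_friend = alpha_friend),
            class = "risk_params", model = "revised")
}

#' @rdname original_params
#' @export
pt_params <- function(alpha, gamma, beta) {
  if (alpha <= 0) stop("`alpha` must be positive")
  if (beta < 0) stop("`beta` must be non-negative")
  if (gamma <= 0 || gamma > 1.5) stop("`gamma` must be in (0, 1.5]")
  structure(list(alpha = alpha, gamma = gamma, beta = beta),
            class = "risk_params", model = "prospect")
}

#' Power-function expected utility of a lottery
#'
#' `EU = p * v^alpha`: the win probability times the dollar amount raised to
#' the risk exponent. Utilities are computed on raw dollar amounts; the
#' inverse-noise scale absorbs units.
#'
#' @param lottery A [lottery()] or any data frame with `p_win` and `amount`
#'   columns (vectorized over rows).
#' @param alpha Risk exponent, > 0.
#' @return Numeric vector of expected utilities.
#' @export
expected_utility <- function(lottery, alpha) {
  stopifnot(is.data.frame(lottery))
  if (!is.numeric(alpha) || any(alpha <= 0)) stop("`alpha` must be positive")
  lottery$p_win * lottery$amount^alpha
}

#' Prospect-theory expected utility (gains only)
#'
#' Applies the one-parameter Tversky-Kahneman probability weighting
#' `pi(p) = p^gamma / (p^gamma + (1 - p)^gamma)^(1/gamma)` to the power
#' utility `v^alpha`. The task has no losses, so there is no loss-aversion
#' term; `gamma = 1` recovers [expected_utility()] exactly.
#'
#' @inheritParams expected_utility
#' @param gamma Probability-weighting curvature in (0, 1.5].
#' @return Numeric vector of weighted utilities.
#' @export
pt_expected_utility <- function(lottery, alpha, gamma) {
  stopifnot(is.data.frame(lottery))
  if (any(gamma <= 0)) stop("`gamma` must be positive")
  pt_probability_weight(lottery$p_win, gamma) * lottery$amount^alpha
}

pt_probability_weight <- function(p, gamma) {
  p^gamma / (p^gamma + (1 - p)^gamma)^(1 / gamma)
}

#' Social-weighted utility of an Opposite-context assignment
#'
#' In the Opposite context the participant keeps one option and their friend
#' receives the other. The utility of an assignment is a weighted average of
#' the participant's own expected utility of the kept option (exponent
#' `alpha`) and the friend's expected utility of the forgone option (fixed
#' exponent `alpha_friend`), mixed by the friend-outcome weight `w`.
#'
#' @param self_option,friend_option Data frames with `p_win` and `amount`
#'   columns (vectorized, equal length): the option assigned to oneself and
#'   the option passed to the friend.
#' @param params A [social_params()] object.
#' @return Numeric vector of mixed utilities.
#' @export
opposite_pair_utility <- function(self_option, friend_option, params) {
  stopifnot(inherits(params, "risk_params"), attr(params, "model") == "revised")
  (1 - params$w) * expected_utility(self_option, params$alpha) +
    params$w * expected_utility(friend_option, params$alpha_friend)
}

#' Logistic probability of choosing the risky option
#'
#' `P(risky) = 1 / (1 + exp(beta * (EU_safe - EU_risky)))`. Computed through
#' `plogis()` so it is numerically stable for arbitrarily large
#' `beta * (EU_risky - EU_safe)`.
#'
#' @param eu_safe,eu_risky Expected utilities of the two options (vectorized).
#' @param beta Inverse decision noise, >= 0. `beta = 0` gives 0.5 (pure
#'   chance) regardless of the utilities.
#' @return Choice probabilities in (0, 1).
#' @export
p_choose_risky <- function(eu_safe, eu_risky, beta) {
  if (any(beta < 0)) stop("`beta` must be non-negative")
  stats::plogis(beta * (eu_risky - eu_safe))
}

# Signed logistic argument beta * (EU_risky-assignment - EU_safe-assignment)
# for a record set under a given model. For the revised model "risky" means
# the risky option is assigned to SELF and the friend implicitly receives the
# safe option (and vice versa). Plain numeric-vector core so likelihood
# evaluation inside the optimizer allocates no data frames.
choice_logit_vec <- function(p, v, s, model, alpha, beta, w = NA, alpha_friend = NA,
                             gamma = NA) {
  if (model == "original") {
    eu_r <- p * v^alpha
    eu_s <- s^alpha
  } else if (model == "revised") {
    eu_r <- (1 - w) * p * v^alpha + w * s^alpha_friend
    eu_s <- (1 - w) * s^alpha + w * p * v^alpha_friend
  } else if (model == "prospect") {
    eu_r <- pt_probability_weight(p, gamma) * v^alpha
    eu_s <- s^alpha
  } else {
    stop("unknown model: ", model)
  }
  beta * (eu_r - eu_s)
}

choice_logit <- function(records, model, params) {
  choice_logit_vec(records$p_win, records$amount, records$safe_amount, model,
                   alpha = params$alpha, beta = params$beta,
                   w = params$w %||% NA, alpha_friend = params$alpha_friend %||% NA,
                   gamma = params$gamma %||% NA)
}

#' Log-likelihood of observed choices under a choice model
#'
#' Sum over trials of the log of the logistic choice probability of the
#' observed choice. Per-trial log-probabilities are evaluated on the log
#' scale directly (never exponentiated), so no underflow occurs even at
#' extreme inverse-noise values.
#'
#' @param records A data frame of choice records: columns `p_win`, `amount`,
#'   `safe_amount`, `chose_risky` (logical).
#' @param model One of `"original"`, `"revised"`, `"prospect"`.
#' @param params Matching parameter container (see [original_params()]).
#' @return The total log-likelihood (<= 0).
#' @export
log_likelihood <- function(records, model = c("original", "revised", "prospect"),
                           params) {
  model <- match.arg(model)
  stopifnot(is.data.frame(records), nrow(records) > 0,
            is.logical(records$chose_risky) || all(records$chose_risky %in% c(0, 1)))
  x <- choice_logit(records, model, params)
  chose <- as.logical(records$chose_risky)
  sum(stats::plogis(ifelse(chose, x, -x), log.p = TRUE))
}

#' Simulate choices over a choice set
#'
#' Draws each trial's choice as a Bernoulli variable with the model's
#' logistic risky-choice probability; seeded and reproducible.
#'
#' @param params Parameter container for `model`.
#' @param model One of `"original"`, `"revised"`, `"prospect"`.
#' @param set A choice set from [build_choice_set()].
#' @param seed Integer seed.
#' @return The choice set with a logical `chose_risky` column appended.
#' @export
simulate_choices <- function(params, model = c("original", "revised", "prospect"),
                             set, seed = 1L) {
  model <- match.arg(model)
  stopifnot(is.data.frame(set), nrow(set) > 0)
  x <- choice_logit(set, model, params)
  p <- stats::plogis(x)
  state <- local_rng_state(seed)
  on.exit(restore_rng_state(state), add = TRUE)
  set$chose_risky <- stats::runif(length(p)) < p
  set
}
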