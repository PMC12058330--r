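# Lottery choice-set construction and its analytic identifiability properties.

#' Experimental conditions
#'
#' The eight blocks of the dyadic risky-choice design: a solo `Baseline`, the
#' joint-outcome `Identical` and adjudicated `Opposite` contexts from the
#' individual session, the four observation-crossed versions from the dyad
#' session, and the `PredictedFriend` block in which the participant predicts
#' their friend's baseline choices (used only to calibrate the friend's risk
#' exponent).
#'
#' @return Character vector of valid condition labels.
#' @export
risk_conditions <- function() {
  c("Baseline", "Identical", "Opposite",
    "ObservedIdentical", "UnobservedIdentical",
    "ObservedOpposite", "UnobservedOpposite",
    "PredictedFriend")
}

#' Conditions belonging to the Opposite (adjudication) context
#'
#' These are the conditions modeled with the social-weighted utility model and
#' subject to the stricter exclusion bound on the risk exponent.
#'
#' @param condition Character vector of condition labels.
#' @return Logical vector, `TRUE` where the condition has Opposite structure.
#' @export
is_opposite_condition <- function(condition) {
  stopifnot(all(condition %in% risk_conditions()))
  grepl("Opposite", condition, fixed = TRUE)
}

#' The lottery design grid
#'
#' Five win probabilities crossed with seven dollar amounts, each played
#' against a certain $5, giving 35 distinct trials per condition.
#'
#' @return A list with elements `p_win`, `amount`, and `safe_amount`.
#' @export
lottery_grid <- function() {
  list(p_win = c(0.10, 0.25, 0.50, 0.75, 0.90),
       amount = c(5, 10, 20, 30, 40, 50, 100),
       safe_amount = 5)
}

#' Construct a lottery
#'
#' A lottery is a single risky prospect: win `amount` dollars with probability
#' `p_win`, else win nothing. The certain option is the degenerate lottery
#' `lottery(1, 5)`.
#'
#' @param p_win Win probability in (0, 1].
#' @param amount Dollar amount, > 0.
#' @return A one-row tibble with columns `p_win` and `amount`.
#' @export
lottery <- function(p_win, amount) {
  stopifnot(is.numeric(p_win), is.numeric(amount), length(p_win) == length(amount))
  if (any(p_win <= 0 | p_win > 1)) stop("`p_win` must be in (0, 1]")
  if (any(amount <= 0)) stop("`amount` must be positive")
  tibble::tibble(p_win = as.numeric(p_win), amount = as.numeric(amount))
}

#' Build the 35-trial choice set for one condition
#'
#' Crosses the design grid (one trial per probability-amount pair), shuffles
#' trial order with the supplied seed, and counterbalances the screen side of
#' the risky option. With 35 trials an exact half/half split is impossible;
#' the assignment is 17/18 with the extra side chosen by the seed.
#'
#' @param condition One of [risk_conditions()].
#' @param seed Integer seed controlling trial order and side assignment.
#' @return A tibble with columns `condition`, `trial_index`, `p_win`,
#'   `amount`, `safe_amount`, `risky_side`.
#' @export
build_choice_set <- function(condition = "Baseline", seed = 1L) {
  condition <- match.arg(condition, risk_conditions())
  grid <- lottery_grid()
  set <- tidyr::expand_grid(p_win = grid$p_win, amount = grid$amount)
  n <- nrow(set)
  state <- local_rng_state(seed)
  on.exit(restore_rng_state(state), add = TRUE)
  ord <- sample.int(n)
  side <- rep(c("left", "right"), length.out = n)[sample.int(n)]
  set <- set[ord, ]
  tibble::tibble(
    condition = condition,
    trial_index = seq_len(n),
    p_win = set$p_win,
    amount = set$amount,
    safe_amount = grid$safe_amount,
    risky_side = side
  )
}

#' Indifference exponent of a risky lottery against a certain amount
#'
#' The exponent `alpha` at which the risky lottery and the certain option
#' have equal power-function expected utility, i.e. the solution of
#' `p * v^alpha = s^alpha`: `alpha = log(1/p) / log(v/s)`. For `v <= s` the
#' risky option is never preferred at any positive exponent and `NA` is
#' returned.
#'
#' @param p_win Win probability (vectorized).
#' @param amount Risky dollar amount (vectorized).
#' @param safe_amount Certain dollar amount (default $5).
#' @return Numeric vector of indifference exponents, `NA` where none exists.
#' @export
indifference_alpha <- function(p_win, amount, safe_amount = 5) {
  stopifnot(all(p_win > 0 & p_win <= 1), all(amount > 0), all(safe_amount > 0))
  out <- ifelse(amount > safe_amount & p_win < 1,
                log(1 / p_win) / log(amount / safe_amount),
                NA_real_)
  as.numeric(out)
}

#' Maximum recoverable risk exponent of a choice set
#'
#' The largest finite indifference exponent across the set's trials. Above
#' this value every noise-free (deterministic) choice vector is identical, so
#' exponents beyond it are not identifiable from choices; it is the analytic
#' basis of the exclusion bound for baseline-context fits.
#'
#' @param set A choice set from [build_choice_set()], or any data frame with
#'   `p_win`, `amount`, `safe_amount` columns.
#' @return The maximum finite indifference exponent; `NA` (with a warning) if
#'   no trial has one.
#' @export
max_recoverable_alpha <- function(set) {
  stopifnot(is.data.frame(set))
  if (nrow(set) == 0) stop("choice set is empty")
  a <- indifference_alpha(set$p_win, set$amount, set$safe_amount)
  if (all(is.na(a))) {
    warning("no trial has an indifference exponent (all risky options dominated)")
    return(NA_real_)
  }
  max(a, na.rm = TRUE)
}

#' Maximum possible simulated earnings of a choice set
#'
#' Sum over trials of the larger of the two options' expected values; the
#' ceiling against which simulated earnings are expressed as a proportion.
#'
#' @inheritParams max_recoverable_alpha
#' @return Total expected value, in dollars, of the EV-maximizing choice
#'   vector.
#' @export
max_possible_earnings <- function(set) {
  stopifnot(is.data.frame(set))
  if (nrow(set) == 0) stop("choice set is empty")
  sum(pmax(set$safe_amount, set$p_win * set$amount))
}

#' Deterministic (noise-free) choice vector at a given exponent
#'
#' The choices of an agent with infinite choice precision: risky whenever its
#' power-function expected utility strictly exceeds the certain option's,
#' equivalently whenever `alpha` exceeds the trial's indifference exponent.
#'
#' @inheritParams max_recoverable_alpha
#' @param alpha Risk exponent, > 0.
#' @return Logical vector, `TRUE` where the risky option is chosen.
#' @export
deterministic_choices <- function(set, alpha) {
  stopifnot(is.data.frame(set), nrow(set) > 0, alpha > 0)
  thr <- indifference_alpha(set$p_win, set$amount, set$safe_amount)
  !is.na(thr) & alpha > thr
}

# Seed a private RNG scope; returns the prior state for restoration.
local_rng_state <- function(seed) {
  state <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  set.seed(seed)
  state
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}
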