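# Per-participant, per-condition maximum-likelihood estimation, AIC, and
# model-based exclusions.
#
# Fits are individual (not hierarchical): each participant x condition record
# set is maximized independently over a bounded box from a multi-start grid,
# because the likelihood is multimodal in (alpha, beta) at low beta.

.fit_bounds <- list(
  alpha = c(0.01, 5),
  beta = c(0.001, 50),
  w = c(0, 1),
  gamma = c(0.2, 1.5)
)

.start_grid <- list(
  alpha = c(0.2, 0.55, 1.0, 1.8),
  beta = c(0.5, 2, 8),
  w = c(0.1, 0.35, 0.7),
  gamma = c(0.6, 1.0, 1.4)
)

# Shared multi-start bounded optimizer. `logit_fn` maps a numeric parameter
# vector to the per-trial signed logistic argument; starts is a data frame
# of start points. The observed-choice signs are folded in once so each
# likelihood evaluation is a single vectorized pass.
multistart_mle <- function(records, logit_fn, starts, lower, upper) {
  sgn <- ifelse(as.logical(records$chose_risky), 1, -1)
  negll <- function(theta) {
    -sum(stats::plogis(sgn * logit_fn(theta), log.p = TRUE))
  }
  runs <- lapply(seq_len(nrow(starts)), function(i) {
    theta0 <- as.numeric(starts[i, ])
    fit <- tryCatch(
      stats::optim(theta0, negll, method = "L-BFGS-B", lower = lower, upper = upper,
                   control = list(maxit = 200)),
      error = function(e) NULL
    )
    fit
  })
  ok <- !vapply(runs, is.null, logical(1))
  if (!any(ok)) {
    return(list(par = as.numeric(starts[1, ]), loglik = -Inf, converged = FALSE,
                n_starts_agreeing = 0L, boundary = NA))
  }
  runs <- runs[ok]
  lls <- -vapply(runs, function(f) f$value, numeric(1))
  best <- which.max(lls)
  par <- runs[[best]]$par
  names(par) <- names(starts)
  boundary <- any(abs(par - lower) < 1e-8 | abs(par - upper) < 1e-8)
  list(
    par = par,
    loglik = lls[best],
    converged = any(vapply(runs, function(f) f$convergence == 0, logical(1))),
    n_starts_agreeing = sum(lls >= lls[best] - 0.01),
    boundary = boundary
  )
}

fit_result_row <- function(participant_id, condition, model, par, extra, res, n) {
  k <- length(par)
  tibble::tibble(
    participant_id = participant_id,
    condition = condition,
    model = model,
    alpha = unname(par["alpha"]),
    beta = unname(par["beta"]),
    w = if ("w" %in% names(par)) unname(par["w"]) else NA_real_,
    gamma = if ("gamma" %in% names(par)) unname(par["gamma"]) else NA_real_,
    alpha_friend = if (is.null(extra$alpha_friend)) NA_real_ else extra$alpha_friend,
    loglik = res$loglik,
    k = k,
    n_trials = n,
    aic = 2 * k - 2 * res$loglik,
    converged = res$converged,
    n_starts_agreeing = res$n_starts_agreeing,
    boundary = res$boundary
  )
}

#' Fit the original expected-utility model to one record set
#'
#' Maximizes the logistic choice likelihood over the risk exponent
#' `alpha` in \[0.01, 5\] and inverse noise `beta` in \[0.001, 50\] from a
#' multi-start grid refined by bounded quasi-Newton (L-BFGS-B); the best
#' start is returned. Boundary estimates are reported as-is and flagged in
#' the `boundary` column, never silently clipped.
#'
#' @param records Choice records for one participant x condition (`p_win`,
#'   `amount`, `safe_amount`, `chose_risky`); at least 10 rows.
#' @param participant_id,condition Optional labels carried into the result.
#' @return A one-row tibble: estimates, `loglik`, `k`, `n_trials`,
#'   `aic = 2k - 2 loglik`, `converged`, `n_starts_agreeing`, `boundary`.
#' @export
fit_original <- function(records, participant_id = NA_character_,
                         condition = NA_character_) {
  check_records(records)
  starts <- expand.grid(alpha = .start_grid$alpha, beta = .start_grid$beta)
  p <- records$p_win; v <- records$amount; s <- records$safe_amount
  res <- multistart_mle(
    records,
    function(th) choice_logit_vec(p, v, s, "original", alpha = th[1], beta = th[2]),
    starts,
    lower = c(.fit_bounds$alpha[1], .fit_bounds$beta[1]),
    upper = c(.fit_bounds$alpha[2], .fit_bounds$beta[2])
  )
  fit_result_row(participant_id, condition, "original", res$par, list(), res,
                 nrow(records))
}

#' Fit the revised (social-weighted) model to Opposite-context records
#'
#' As [fit_original()], with the friend-outcome weight `w` in \[0, 1\] as a
#' third free parameter. The friend exponent `alpha_friend` is held fixed at
#' the supplied per-participant constant (see [estimate_alpha_friend()]) and
#' is never re-fit jointly; `k = 3`.
#'
#' @inheritParams fit_original
#' @param alpha_friend Fixed friend risk exponent, finite and > 0.
#' @return A one-row tibble as for [fit_original()], with `w` and
#'   `alpha_friend` filled in.
#' @export
fit_revised <- function(records, alpha_friend, participant_id = NA_character_,
                        condition = NA_character_) {
  check_records(records)
  if (!is.finite(alpha_friend) || alpha_friend <= 0) {
    stop("`alpha_friend` must be finite and positive")
  }
  starts <- expand.grid(alpha = .start_grid$alpha, beta = .start_grid$beta,
                        w = .start_grid$w)
  p <- records$p_win; v <- records$amount; s <- records$safe_amount
  res <- multistart_mle(
    records,
    function(th) choice_logit_vec(p, v, s, "revised", alpha = th[1], beta = th[2],
                                  w = th[3], alpha_friend = alpha_friend),
    starts,
    lower = c(.fit_bounds$alpha[1], .fit_bounds$beta[1], .fit_bounds$w[1]),
    upper = c(.fit_bounds$alpha[2], .fit_bounds$beta[2], .fit_bounds$w[2])
  )
  fit_result_row(participant_id, condition, "revised", res$par,
                 list(alpha_friend = alpha_friend), res, nrow(records))
}

#' Fit the prospect-theory comparison model
#'
#' A gains-only prospect-theory alternative (power utility plus one-parameter
#' probability weighting) used only as a comparison candidate in the AIC
#' harness; `k = 3`.
#'
#' @inheritParams fit_original
#' @return A one-row tibble as for [fit_original()], with `gamma` filled in.
#' @export
fit_prospect <- function(records, participant_id = NA_character_,
                         condition = NA_character_) {
  check_records(records)
  starts <- expand.grid(alpha = .start_grid$alpha, beta = .start_grid$beta,
                        gamma = .start_grid$gamma)
  p <- records$p_win; v <- records$amount; s <- records$safe_amount
  res <- multistart_mle(
    records,
    function(th) choice_logit_vec(p, v, s, "prospect", alpha = th[1], beta = th[2],
                                  gamma = th[3]),
    starts,
    lower = c(.fit_bounds$alpha[1], .fit_bounds$beta[1], .fit_bounds$gamma[1]),
    upper = c(.fit_bounds$alpha[2], .fit_bounds$beta[2], .fit_bounds$gamma[2])
  )
  fit_result_row(participant_id, condition, "prospect", res$par, list(), res,
                 nrow(records))
}

check_records <- function(records) {
  stopifnot(is.data.frame(records))
  if (nrow(records) < 10) {
    stop("need at least 10 choice records to fit a choice model, got ", nrow(records))
  }
  req <- c("p_win", "amount", "safe_amount", "chose_risky")
  missing <- setdiff(req, names(records))
  if (length(missing)) stop("records are missing columns: ", paste(missing, collapse = ", "))
  invisible(records)
}

#' Estimate a participant's belief about their friend's risk exponent
#'
#' Fits the original model to the participant's trial-by-trial predictions of
#' their friend's baseline choices; the fitted `alpha` becomes the
#' individualized `alpha_friend` constant used by [fit_revised()].
#'
#' @param predicted_friend_records Choice records from the predicted-friend
#'   block.
#' @inheritParams fit_original
#' @return The fitted exponent, with the full fit row attached as attribute
#'   `"fit"` (use it to check the chance-AIC reliability of the estimate).
#' @export
estimate_alpha_friend <- function(predicted_friend_records,
                                  participant_id = NA_character_) {
  fit <- fit_original(predicted_friend_records, participant_id, "PredictedFriend")
  structure(fit$alpha, fit = fit)
}

#' AIC of a chance (coin-flip) decision maker
#'
#' A chance decision maker picks every option at probability 0.5, giving
#' log-likelihood `n * log(0.5)` and AIC `2k - 2 n log(0.5)`. A pure
#' coin-flip model has no free parameters (`k = 0`, the exclusion-rule
#' comparator); supply `k` to place the chance value on another penalty
#' convention.
#'
#' @param n_trials Number of trials in the condition.
#' @param k Parameter penalty applied to the chance model.
#' @return The chance AIC value.
#' @export
chance_aic <- function(n_trials, k = 0) {
  stopifnot(n_trials > 0, k >= 0)
  2 * k - 2 * n_trials * log(0.5)
}

#' Exclusion rule configuration
#'
#' Defaults encode the model-based exclusion rules: in Baseline/Identical
#' contexts, exclude fits with `alpha` above the choice set's maximum
#' recoverable exponent (3.32); in Opposite contexts, exclude `alpha` above 2
#' (choice vectors generated by exponents above 2 differ by at most one
#' choice, and recovery is best on \[0, 2\]) or a friend weight below 1e-6;
#' in all contexts, exclude fits whose AIC is at or beyond the chance AIC.
#'
#' @param alpha_max_baseline_identical Exponent bound for Baseline/Identical
#'   context fits.
#' @param alpha_max_opposite Exponent bound for Opposite-context fits.
#' @param w_min Minimum friend weight for Opposite-context fits.
#' @param aic_vs_chance Apply the chance-AIC rule?
#' @return A list of class `exclusion_config`.
#' @export
exclusion_config <- function(alpha_max_baseline_identical = 3.32,
                             alpha_max_opposite = 2,
                             w_min = 1e-6,
                             aic_vs_chance = TRUE) {
  stopifnot(alpha_max_baseline_identical > 0, alpha_max_opposite > 0, w_min > 0)
  structure(list(alpha_max_baseline_identical = alpha_max_baseline_identical,
                 alpha_max_opposite = alpha_max_opposite,
                 w_min = w_min,
                 aic_vs_chance = isTRUE(aic_vs_chance)),
            class = "exclusion_config")
}

#' Apply model-based exclusion rules to a table of fits
#'
#' Flags each participant x condition fit against the bounds in
#' [exclusion_config()]. Exclusions apply per condition, not
#' participant-wide. The chance-AIC comparison uses `>=` against
#' `chance_aic(n, k = 0)`: a chance decision maker has no free parameters,
#' so the fitted model is flagged unless its likelihood beats chance by more
#' than its own parameter penalty. (With a same-`k` comparator the rule
#' could never trigger, since the chance model is nested in every fitted
#' model at `beta = 0`.)
#'
#' @param fits A tibble of fit rows ([fit_original()] / [fit_revised()]),
#'   with `condition` set to a valid label.
#' @param config An [exclusion_config()].
#' @return A tibble: `participant_id`, `condition`, `excluded`, `reasons`
#'   (semicolon-separated subset of `alpha_bound`, `w_bound`, `aic_chance`).
#' @export
apply_exclusions <- function(fits, config = exclusion_config()) {
  stopifnot(is.data.frame(fits), inherits(config, "exclusion_config"))
  if (any(!fits$condition %in% risk_conditions())) {
    bad <- setdiff(unique(fits$condition), risk_conditions())
    stop("unknown condition(s): ", paste(bad, collapse = ", "))
  }
  opp <- is_opposite_condition(fits$condition)
  alpha_cap <- ifelse(opp, config$alpha_max_opposite,
                      config$alpha_max_baseline_identical)
  reasons <- mapply(function(alpha, w, aic, n, k, is_opp, cap) {
    r <- character(0)
    if (alpha > cap) r <- c(r, "alpha_bound")
    if (is_opp && !is.na(w) && w < config$w_min) r <- c(r, "w_bound")
    if (config$aic_vs_chance && aic >= chance_aic(n, k = 0)) r <- c(r, "aic_chance")
    paste(r, collapse = ";")
  }, fits$alpha, fits$w, fits$aic, fits$n_trials, fits$k, opp, alpha_cap)
  tibble::tibble(
    participant_id = fits$participant_id,
    condition = fits$condition,
    excluded = nzchar(reasons),
    reasons = unname(reasons)
  )
}
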