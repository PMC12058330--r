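# Parameter-recovery and model-comparison harnesses.

#' Run a parameter-recovery simulation
#'
#' Draws `n_agents` true parameter vectors, simulates one 35-trial condition
#' per agent (an Opposite-context block for the revised model, a Baseline
#' block otherwise), refits with the matching fitter and reports true-vs-
#' fitted correlation, bias and RMSE per free parameter. True exponents are
#' drawn uniformly over `alpha_range`, friend weights uniformly over
#' `w_range`, inverse noise from LogNormal(`beta_meanlog`, `beta_sdlog`),
#' and (for the revised model) the fixed friend exponent from the same
#' truncated normal the cohort generator uses for baseline exponents.
#'
#' @param model `"original"` or `"revised"`.
#' @param n_agents Number of simulated agents.
#' @param alpha_range Uniform range for true exponents.
#' @param w_range Uniform range for true friend weights (revised only).
#' @param beta_meanlog,beta_sdlog Log-normal inverse-noise parameters.
#' @param beta_fixed Optional fixed inverse noise overriding the log-normal
#'   draw (useful for identifiability checks at low noise).
#' @param alpha_friend_mean,alpha_friend_sd,alpha_friend_trunc Truncated
#'   normal for the fixed friend exponents (revised only).
#' @param seed Integer seed.
#' @return A list of class `recovery_report`: `draws` (true and fitted
#'   values per agent), `summary` (per-parameter correlation, bias, RMSE)
#'   and `settings` (everything needed to reproduce the run).
#' @export
run_parameter_recovery <- function(model = c("revised", "original"),
                                   n_agents = 200,
                                   alpha_range = c(0, 2),
                                   w_range = c(0.05, 0.95),
                                   beta_meanlog = log(3),
                                   beta_sdlog = 0.5,
                                   beta_fixed = NULL,
                                   alpha_friend_mean = 0.55,
                                   alpha_friend_sd = 0.23,
                                   alpha_friend_trunc = c(0.05, 2),
                                   seed = 1L) {
  model <- match.arg(model)
  stopifnot(n_agents >= 2, alpha_range[1] >= 0, alpha_range[2] <= .fit_bounds$alpha[2])
  settings <- list(model = model, n_agents = n_agents, alpha_range = alpha_range,
                   w_range = w_range, beta_meanlog = beta_meanlog,
                   beta_sdlog = beta_sdlog, beta_fixed = beta_fixed,
                   alpha_friend_mean = alpha_friend_mean,
                   alpha_friend_sd = alpha_friend_sd,
                   alpha_friend_trunc = alpha_friend_trunc, seed = seed)
  state <- local_rng_state(seed)
  on.exit(restore_rng_state(state), add = TRUE)
  true_alpha <- pmax(stats::runif(n_agents, alpha_range[1], alpha_range[2]),
                     .fit_bounds$alpha[1])
  true_beta <- if (is.null(beta_fixed)) {
    stats::rlnorm(n_agents, beta_meanlog, beta_sdlog)
  } else {
    rep(beta_fixed, n_agents)
  }
  if (model == "revised") {
    true_w <- stats::runif(n_agents, w_range[1], w_range[2])
    alpha_friend <- rnorm_trunc(n_agents, alpha_friend_mean, alpha_friend_sd,
                                alpha_friend_trunc[1], alpha_friend_trunc[2])
  }
  cond <- if (model == "revised") "Opposite" else "Baseline"
  seeds <- matrix(sample.int(.Machine$integer.max - 1L, 2L * n_agents), ncol = 2)

  rows <- vector("list", n_agents)
  for (i in seq_len(n_agents)) {
    set <- build_choice_set(cond, seed = seeds[i, 1])
    if (model == "revised") {
      params <- social_params(true_alpha[i], true_beta[i], true_w[i], alpha_friend[i])
      rec <- simulate_choices(params, "revised", set, seed = seeds[i, 2])
      fit <- fit_revised(rec, alpha_friend[i], sprintf("sim%03d", i), cond)
    } else {
      params <- original_params(true_alpha[i], true_beta[i])
      rec <- simulate_choices(params, "original", set, seed = seeds[i, 2])
      fit <- fit_original(rec, sprintf("sim%03d", i), cond)
    }
    fit$true_alpha <- true_alpha[i]
    fit$true_beta <- true_beta[i]
    fit$true_w <- if (model == "revised") true_w[i] else NA_real_
    rows[[i]] <- fit
  }
  draws <- dplyr::bind_rows(rows)

  params_to_score <- c("alpha", "beta", if (model == "revised") "w")
  summary <- dplyr::bind_rows(lapply(params_to_score, function(p) {
    truth <- draws[[paste0("true_", p)]]
    fitted <- draws[[p]]
    tibble::tibble(parameter = p,
                   correlation = if (stats::sd(truth) == 0 || stats::sd(fitted) == 0) {
                     NA_real_ # undefined when either side is constant
                   } else {
                     stats::cor(truth, fitted)
                   },
                   bias = mean(fitted - truth),
                   rmse = sqrt(mean((fitted - truth)^2)))
  }))
  structure(list(draws = draws, summary = summary, settings = settings),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  s <- x$settings
  cat(sprintf("Parameter recovery: %s model, %d agents, seed %d\n",
              s$model, s$n_agents, s$seed))
  cat(sprintf("  true alpha ~ U(%.2f, %.2f)", s$alpha_range[1], s$alpha_range[2]))
  if (s$model == "revised") {
    cat(sprintf(", w ~ U(%.2f, %.2f)", s$w_range[1], s$w_range[2]))
  }
  cat("\n")
  for (i in seq_len(nrow(x$summary))) {
    r <- x$summary[i, ]
    cat(sprintf("  %-6s r = %.3f  bias = %+.3f  rmse = %.3f\n",
                r$parameter, r$correlation, r$bias, r$rmse))
  }
  invisible(x)
}

#' Write a recovery report to disk
#'
#' Serializes the per-agent draws to CSV and the summary to a short
#' human-readable text file.
#'
#' @param report A [run_parameter_recovery()] result.
#' @param path_prefix File path prefix; writes `<prefix>_draws.csv` and
#'   `<prefix>_summary.txt`.
#' @return Invisibly, the paths written.
#' @export
write_recovery_report <- function(report, path_prefix) {
  stopifnot(inherits(report, "recovery_report"))
  draws_path <- paste0(path_prefix, "_draws.csv")
  txt_path <- paste0(path_prefix, "_summary.txt")
  readr::write_csv(report$draws, draws_path)
  txt <- utils::capture.output(print(report))
  writeLines(txt, txt_path)
  invisible(c(draws = draws_path, summary = txt_path))
}

#' Compare choice models by AIC across participants
#'
#' Fits each candidate model to every participant x condition record set in
#' a long trial table and tallies, per condition family, how often each
#' model attains the lowest AIC. Ties are broken by the order in which the
#' candidates are listed and flagged.
#'
#' @param trials Long trial table (`participant_id`, `condition`, trial
#'   columns, `chose_risky`).
#' @param models Character vector of at least two candidates from
#'   `"original"`, `"revised"`, `"prospect"`.
#' @param alpha_friend Fixed friend exponents for the revised model: a
#'   single value, or a named vector keyed by `participant_id`. If `NULL`
#'   and the table contains a `PredictedFriend` block, each participant's
#'   constant is estimated from it.
#' @return A list of class `model_comparison`: `aic_table` (participant,
#'   condition, model, aic, winner, tie) and `winners` (counts per condition
#'   family x model).
#' @export
compare_models <- function(trials, models = c("original", "revised"),
                           alpha_friend = NULL) {
  stopifnot(is.data.frame(trials), length(models) >= 2)
  if (anyDuplicated(models)) {
    warning("duplicated candidate models; ties broken by listed order")
  }
  fit_conditions <- setdiff(unique(trials$condition), "PredictedFriend")
  ids <- unique(trials$participant_id)

  af_for <- function(id) {
    if (is.null(alpha_friend)) {
      pf <- trials[trials$participant_id == id & trials$condition == "PredictedFriend", ]
      if (nrow(pf) == 0) stop("no `alpha_friend` supplied and no PredictedFriend block for ", id)
      as.numeric(estimate_alpha_friend(pf, id))
    } else if (length(alpha_friend) == 1 && is.null(names(alpha_friend))) {
      alpha_friend
    } else {
      unname(alpha_friend[[id]])
    }
  }

  rows <- list()
  for (id in ids) {
    af <- if ("revised" %in% models) af_for(id) else NA_real_
    for (cond in fit_conditions) {
      rec <- trials[trials$participant_id == id & trials$condition == cond, ]
      if (nrow(rec) == 0) next
      aics <- vapply(models, function(m) {
        fit <- switch(m,
                      original = fit_original(rec, id, cond),
                      revised = fit_revised(rec, af, id, cond),
                      prospect = fit_prospect(rec, id, cond),
                      stop("unknown model: ", m))
        fit$aic
      }, numeric(1))
      best <- which.min(aics) # which.min takes the first minimum: listed order
      rows[[length(rows) + 1]] <- tibble::tibble(
        participant_id = id, condition = cond, model = models,
        aic = unname(aics),
        winner = seq_along(models) == best,
        tie = sum(aics == min(aics)) > 1
      )
    }
  }
  aic_table <- dplyr::bind_rows(rows)
  winners <- aic_table |>
    dplyr::filter(.data$winner) |>
    dplyr::mutate(family = ifelse(is_opposite_condition(.data$condition),
                                  "Opposite", "BaselineIdentical")) |>
    dplyr::count(.data$family, .data$model, name = "n_wins")
  structure(list(aic_table = aic_table, winners = winners),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("Model comparison (AIC winner counts per condition family)\n")
  print(as.data.frame(x$winners), row.names = FALSE)
  invisible(x)
}
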