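# Independent oracles and small fixture builders used across test files.

# Brute-force likelihood: per-trial probability of the observed choice
# evaluated directly from the model formulas (symmetric logistic form, no
# log-scale shortcuts), summed on the log scale trial by trial.
oracle_loglik <- function(records, model, params) {
  total <- 0
  for (i in seq_len(nrow(records))) {
    p <- records$p_win[i]
    v <- records$amount[i]
    s <- records$safe_amount[i]
    if (model == "original") {
      eu_r <- p * v^params$alpha
      eu_s <- s^params$alpha
    } else if (model == "revised") {
      eu_r <- (1 - params$w) * p * v^params$alpha + params$w * s^params$alpha_friend
      eu_s <- (1 - params$w) * s^params$alpha + params$w * p * v^params$alpha_friend
    } else if (model == "prospect") {
      pg <- p^params$gamma / (p^params$gamma + (1 - p)^params$gamma)^(1 / params$gamma)
      eu_r <- pg * v^params$alpha
      eu_s <- s^params$alpha
    } else {
      stop("unknown model")
    }
    d <- params$beta * (eu_s - eu_r) # argument for P(chose risky)
    pr_obs <- if (records$chose_risky[i]) 1 / (1 + exp(d)) else 1 / (1 + exp(-d))
    total <- total + log(pr_obs)
  }
  total
}

# Random record set on the standard grid with choices from a coin flip.
random_records <- function(n = 35, seed = 1) {
  set <- build_choice_set("Baseline", seed = seed)[seq_len(n), ]
  set$chose_risky <- withr::with_seed(seed + 1000, stats::runif(n) < 0.5)
  set
}

# Draw parameters in the range where both the oracle's direct evaluation and
# the implementation are exact in double precision (|beta * dEU| < 700).
random_params <- function(model, seed) {
  withr::with_seed(seed, {
    alpha <- stats::runif(1, 0.2, 1.2)
    beta <- stats::runif(1, 0, 3)
    switch(model,
      original = original_params(alpha, beta),
      revised = social_params(alpha, beta, stats::runif(1), stats::runif(1, 0.2, 1.2)),
      prospect = pt_params(alpha, stats::runif(1, 0.3, 1.5), beta)
    )
  })
}

# Tiny dyad cohort table for GAM tests: one row per participant with a known
# mean structure over age.
make_age_table <- function(n_dyads = 32, f = function(age) 0 * age, sd = 0.1,
                           seed = 1, conditions = "A") {
  withr::with_seed(seed, {
    age <- stats::runif(2 * n_dyads, 12, 22.8)
    base <- tibble::tibble(
      participant_id = sprintf("P%03d", seq_len(2 * n_dyads)),
      dyad_id = sprintf("D%02d", rep(seq_len(n_dyads), each = 2)),
      age = age
    )
    dplyr::bind_rows(lapply(conditions, function(cc) {
      out <- base
      out$condition <- cc
      out$y <- f(out$age) + stats::rnorm(nrow(out), 0, sd)
      out
    }))
  })
}
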