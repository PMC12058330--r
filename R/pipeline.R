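# Orchestration: trial-table I/O, configuration, and the staged analysis
# pipeline (fit -> exclude -> behavior -> age trends).

#' Read and validate a long-format trial table
#'
#' Expects a CSV with columns `participant_id`, `dyad_id`, `age`,
#' `condition`, `trial_index`, `p_win`, `amount`, `safe_amount`,
#' `chose_risky` (`risky_side` is optional). Validates condition labels,
#' dyad sizes (exactly two members), and membership of probabilities in the
#' design grid. Lines starting with `#` (config-hash headers) are skipped.
#'
#' @param path Path to the CSV file.
#' @param off_grid What to do with rows whose `p_win` is not in the design
#'   grid: `"warn"` (keep, default), `"error"`, or `"drop"` (each drop is
#'   reported).
#' @return A validated tibble.
#' @export
read_trial_table <- function(path, off_grid = c("warn", "error", "drop")) {
  off_grid <- match.arg(off_grid)
  trials <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                            progress = FALSE)
  required <- c("participant_id", "dyad_id", "age", "condition", "trial_index",
                "p_win", "amount", "safe_amount", "chose_risky")
  missing <- setdiff(required, names(trials))
  if (length(missing)) {
    stop("trial table is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  bad_cond <- !trials$condition %in% risk_conditions()
  if (any(bad_cond)) {
    stop("unknown condition label(s) at row(s) ",
         paste(utils::head(which(bad_cond), 5), collapse = ", "), ": ",
         paste(unique(trials$condition[bad_cond]), collapse = ", "))
  }
  if (!is.logical(trials$chose_risky)) {
    if (!all(trials$chose_risky %in% c(0, 1, NA))) {
      stop("`chose_risky` must be logical or 0/1")
    }
    trials$chose_risky <- as.logical(trials$chose_risky)
  }
  sizes <- tapply(trials$participant_id, trials$dyad_id,
                  function(p) length(unique(p)))
  if (any(sizes != 2)) {
    stop("dyad(s) without exactly two members: ",
         paste(names(sizes)[sizes != 2], collapse = ", "))
  }
  grid <- lottery_grid()
  off <- !trials$p_win %in% grid$p_win
  if (any(off)) {
    msg <- paste0(sum(off), " row(s) have off-grid win probabilities (e.g. row ",
                  which(off)[1], ", p_win = ", trials$p_win[which(off)[1]], ")")
    if (off_grid == "error") stop(msg)
    if (off_grid == "drop") {
      message(msg, "; dropped")
      trials <- trials[!off, ]
    } else {
      warning(msg, "; kept")
    }
  }
  trials
}

#' Pipeline configuration
#'
#' A fully serializable description of one analysis run: either a path to a
#' trial-table CSV or a synthetic-cohort configuration, the exclusion rules,
#' band settings, the output directory and the global seed. A run is
#' reproducible from its config and seed alone.
#'
#' @param input Path to a trial CSV, or `NULL` to simulate from `cohort`.
#' @param cohort A [cohort_config()] used when `input` is `NULL`.
#' @param exclusions An [exclusion_config()].
#' @param apply_exclusions Set `FALSE` to run the full-sample sensitivity
#'   mode in which no participant is excluded.
#' @param out_dir Output directory (created if needed); `NULL` for none.
#' @param seed Global seed.
#' @param n_draws Posterior draws for simultaneous bands.
#' @param k Spline basis dimension.
#' @param write_figures Write band figures (PDF) alongside the CSVs?
#' @param verbose Log stage progress to stderr?
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(input = NULL,
                            cohort = cohort_config(),
                            exclusions = exclusion_config(),
                            apply_exclusions = TRUE,
                            out_dir = NULL,
                            seed = 1L,
                            n_draws = 10000,
                            k = 10,
                            write_figures = FALSE,
                            verbose = TRUE) {
  structure(list(input = input, cohort = cohort, exclusions = exclusions,
                 apply_exclusions = isTRUE(apply_exclusions),
                 out_dir = out_dir, seed = as.integer(seed),
                 n_draws = n_draws, k = k,
                 write_figures = isTRUE(write_figures),
                 verbose = isTRUE(verbose)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Recognized top-level keys mirror the [pipeline_config()] arguments;
#' `cohort` and `exclusions` may be nested maps of the corresponding
#' constructor arguments.
#'
#' @param path Path to a YAML file.
#' @return A `pipeline_config` object.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y[setdiff(names(y), c("cohort", "exclusions"))]
  if (!is.null(y$cohort)) args$cohort <- do.call(cohort_config, y$cohort)
  if (!is.null(y$exclusions)) args$exclusions <- do.call(exclusion_config, y$exclusions)
  do.call(pipeline_config, args)
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yml")
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(lapply(unclass(config), function(x) {
    if (inherits(x, "cohort_config") || inherits(x, "exclusion_config")) unclass(x) else x
  })), tmp)
  unname(tools::md5sum(tmp))
}

write_stage_csv <- function(df, path, hash) {
  writeLines(paste0("# config_hash: ", hash), path)
  readr::write_csv(df, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

log_stage <- function(config, ...) {
  if (config$verbose) message("[dyadrisk] ", ...)
}

# Fit every participant x condition block of a trial table. Baseline and
# Identical-context blocks (and PredictedFriend) use the original model;
# Opposite-context blocks use the revised model with the participant's
# alpha_friend constant estimated from their PredictedFriend block.
fit_all_participants <- function(trials, conditions = setdiff(unique(trials$condition),
                                                              "PredictedFriend")) {
  ids <- unique(trials$participant_id)
  af <- vapply(ids, function(id) {
    pf <- trials[trials$participant_id == id & trials$condition == "PredictedFriend", ]
    if (nrow(pf) == 0) return(NA_real_)
    as.numeric(estimate_alpha_friend(pf, id))
  }, numeric(1))
  names(af) <- ids
  rows <- list()
  for (id in ids) {
    for (cond in intersect(conditions, unique(trials$condition))) {
      rec <- trials[trials$participant_id == id & trials$condition == cond, ]
      if (nrow(rec) == 0) next
      fit <- if (is_opposite_condition(cond)) {
        if (is.na(af[[id]])) {
          stop("participant ", id, " has Opposite-context data but no ",
               "PredictedFriend block to calibrate alpha_friend")
        }
        fit_revised(rec, af[[id]], id, cond)
      } else {
        fit_original(rec, id, cond)
      }
      rows[[length(rows) + 1]] <- fit
    }
  }
  list(fits = dplyr::bind_rows(rows), alpha_friend = af)
}

#' Run the full analysis pipeline
#'
#' Executes the staged analysis on a trial table (read from
#' `config$input`, or simulated from `config$cohort`): per-participant model
#' fits, model-based exclusions, behavioral summaries, and the four age
#' analyses — (1) baseline age trend of the risk exponent and earnings via
#' first-derivative simultaneous bands, (2) Identical-vs-Baseline and
#' Opposite-vs-Baseline difference smooths (Opposite and Identical are
#' never contrasted directly), (3) observation contrasts within each
#' context using a 4-level condition factor, and (4) the age trend of the
#' friend weight. Stage outputs are written as CSVs (with a config-hash
#' header) under `config$out_dir` when set.
#'
#' @param config A [pipeline_config()].
#' @return A report bundle (list) with elements `trials`, `cohort` (truth
#'   table when simulated), `alpha_friend`, `fits`, `flags`, `behavior`,
#'   `analyses`, `config`, `hash`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  hash <- config_hash(config)
  bundle <- list(config = config, hash = hash)

  if (is.null(config$input)) {
    log_stage(config, "simulating synthetic cohort (", config$cohort$n_dyads, " dyads)")
    cohort <- generate_cohort(config$cohort, seed = config$seed)
    trials <- generate_study_dataset(cohort, seed = config$seed + 1L)
    bundle$cohort <- cohort
  } else {
    log_stage(config, "reading trial table from ", config$input)
    trials <- read_trial_table(config$input)
  }
  bundle$trials <- trials

  log_stage(config, "fitting choice models per participant x condition")
  fitted <- fit_all_participants(trials)
  fits <- fitted$fits
  bundle$alpha_friend <- tibble::tibble(participant_id = names(fitted$alpha_friend),
                                        alpha_friend = unname(fitted$alpha_friend))
  bundle$fits <- fits

  log_stage(config, "applying model-based exclusions")
  flags <- apply_exclusions(fits, config$exclusions)
  if (!config$apply_exclusions) flags$excluded <- FALSE
  bundle$flags <- flags

  log_stage(config, "computing behavioral summaries")
  behavior <- trials |>
    dplyr::filter(.data$condition != "PredictedFriend") |>
    dplyr::group_by(.data$participant_id, .data$dyad_id, .data$age, .data$condition) |>
    dplyr::group_modify(function(rec, key) {
      tibble::tibble(prop_risky = proportion_risky(rec),
                     earnings = simulated_earnings(rec),
                     earnings_prop = earnings_proportion(rec))
    }) |>
    dplyr::ungroup()
  bundle$behavior <- behavior

  meta <- dplyr::distinct(trials, .data$participant_id, .data$dyad_id, .data$age)
  keep <- dplyr::filter(flags, !.data$excluded)[, c("participant_id", "condition")]
  fits_kept <- dplyr::inner_join(fits, keep, by = c("participant_id", "condition")) |>
    dplyr::inner_join(meta, by = "participant_id")
  behavior_kept <- dplyr::inner_join(
    behavior, keep, by = c("participant_id", "condition"))

  analyses <- list()

  # Q1: baseline age trends (risk exponent, Gaussian; earnings, Beta family)
  log_stage(config, "Q1: baseline age trend")
  base_alpha <- dplyr::filter(fits_kept, .data$condition == "Baseline")
  fit_a <- fit_age_smooth(base_alpha, "alpha", k = config$k)
  band_a <- derivative_simultaneous_band(fit_a, n_points = 100,
                                         n_draws = config$n_draws,
                                         seed = config$seed)
  base_earn <- dplyr::filter(behavior_kept, .data$condition == "Baseline")
  fit_e <- fit_proportion_model(base_earn, "earnings_prop", k = config$k)
  band_e <- derivative_simultaneous_band(fit_e, n_points = 100,
                                         n_draws = config$n_draws,
                                         seed = config$seed)
  analyses$baseline <- list(
    alpha_fit = fit_a, alpha_derivative = band_a,
    alpha_windows = significant_windows(band_a),
    earnings_fit = fit_e, earnings_derivative = band_e,
    earnings_windows = significant_windows(band_e)
  )

  # Q2: context vs. baseline difference smooths (never Opposite vs Identical)
  log_stage(config, "Q2: Identical / Opposite vs Baseline differences")
  q2 <- list()
  for (ctx in c("Identical", "Opposite")) {
    d_alpha <- dplyr::filter(fits_kept, .data$condition %in% c("Baseline", ctx))
    f <- fit_age_smooth(d_alpha, "alpha", k = config$k)
    band <- difference_smooth(f, ctx, "Baseline", n_draws = config$n_draws,
                              seed = config$seed)
    d_earn <- dplyr::filter(behavior_kept, .data$condition %in% c("Baseline", ctx))
    fe <- fit_proportion_model(d_earn, "earnings_prop", k = config$k)
    band_e2 <- difference_smooth(fe, ctx, "Baseline", n_draws = config$n_draws,
                                 seed = config$seed)
    q2[[ctx]] <- list(alpha_fit = f, alpha_diff = band,
                      alpha_windows = significant_windows(band),
                      earnings_fit = fe, earnings_diff = band_e2,
                      earnings_windows = significant_windows(band_e2))
  }
  analyses$context_vs_baseline <- q2

  # Q3: observation contrasts within context, 4-level condition factor
  log_stage(config, "Q3: observation contrasts")
  part2 <- c("ObservedIdentical", "UnobservedIdentical",
             "ObservedOpposite", "UnobservedOpposite")
  q3_alpha <- dplyr::filter(fits_kept, .data$condition %in% part2)
  q3 <- list()
  if (length(unique(q3_alpha$condition)) == 4) {
    f3 <- fit_age_smooth(q3_alpha, "alpha", k = config$k)
    q3$alpha_fit <- f3
    q3$identical_obs_diff <- difference_smooth(
      f3, "ObservedIdentical", "UnobservedIdentical",
      n_draws = config$n_draws, seed = config$seed)
    q3$opposite_obs_diff <- difference_smooth(
      f3, "ObservedOpposite", "UnobservedOpposite",
      n_draws = config$n_draws, seed = config$seed)
    q3$identical_obs_windows <- significant_windows(q3$identical_obs_diff)
    q3$opposite_obs_windows <- significant_windows(q3$opposite_obs_diff)
  }
  analyses$observation <- q3

  # Q4: age trend of the friend weight (Opposite-context fits only)
  log_stage(config, "Q4: friend-weight age trend")
  w_data <- dplyr::filter(fits_kept, .data$condition == "Opposite")
  fit_w <- fit_age_smooth(w_data, "w", k = config$k)
  band_w <- derivative_simultaneous_band(fit_w, n_points = 100,
                                         n_draws = config$n_draws,
                                         seed = config$seed)
  analyses$friend_weight <- list(
    fit = fit_w, derivative = band_w,
    windows = significant_windows(band_w),
    smooth_table = smooth_terms(fit_w)
  )

  bundle$analyses <- analyses

  if (!is.null(config$out_dir)) {
    write_bundle(bundle, config$out_dir)
  }
  invisible(bundle)
}

# Serialize a pipeline bundle: stage CSVs (config-hash header), band CSVs,
# optional figures, and a plain-text summary.
write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- bundle$hash
  p <- function(...) file.path(out_dir, ...)
  if (!is.null(bundle$cohort)) write_stage_csv(bundle$cohort, p("cohort_truth.csv"), hash)
  write_stage_csv(bundle$trials, p("trials.csv"), hash)
  write_stage_csv(bundle$fits, p("fits.csv"), hash)
  write_stage_csv(bundle$flags, p("exclusion_flags.csv"), hash)
  write_stage_csv(bundle$behavior, p("behavior.csv"), hash)
  write_stage_csv(bundle$alpha_friend, p("alpha_friend.csv"), hash)

  bands <- list(
    baseline_alpha_derivative = bundle$analyses$baseline$alpha_derivative,
    baseline_earnings_derivative = bundle$analyses$baseline$earnings_derivative,
    identical_vs_baseline_alpha = bundle$analyses$context_vs_baseline$Identical$alpha_diff,
    opposite_vs_baseline_alpha = bundle$analyses$context_vs_baseline$Opposite$alpha_diff,
    identical_vs_baseline_earnings = bundle$analyses$context_vs_baseline$Identical$earnings_diff,
    opposite_vs_baseline_earnings = bundle$analyses$context_vs_baseline$Opposite$earnings_diff,
    friend_weight_derivative = bundle$analyses$friend_weight$derivative
  )
  if (!is.null(bundle$analyses$observation$identical_obs_diff)) {
    bands$identical_observation <- bundle$analyses$observation$identical_obs_diff
    bands$opposite_observation <- bundle$analyses$observation$opposite_obs_diff
  }
  for (nm in names(bands)) {
    b <- bands[[nm]]
    df <- tibble::as_tibble(b)
    df$excludes_zero <- df$lower > 0 | df$upper < 0
    write_stage_csv(df, p(paste0("band_", nm, ".csv")), hash)
    if (bundle$config$write_figures) {
      plot_band_pdf(b, p(paste0("band_", nm, ".pdf")))
    }
  }

  summary_lines <- c(
    paste0("dyadrisk pipeline summary (config hash ", hash, ")"),
    sprintf("participants: %d; fits: %d; excluded fits: %d (%.1f%%)",
            length(unique(bundle$trials$participant_id)), nrow(bundle$fits),
            sum(bundle$flags$excluded),
            100 * mean(bundle$flags$excluded)),
    "",
    "significant age windows (simultaneous 95% bands):",
    window_lines("baseline alpha derivative", bundle$analyses$baseline$alpha_windows),
    window_lines("identical vs baseline alpha", bundle$analyses$context_vs_baseline$Identical$alpha_windows),
    window_lines("opposite vs baseline alpha", bundle$analyses$context_vs_baseline$Opposite$alpha_windows),
    window_lines("friend-weight derivative", bundle$analyses$friend_weight$windows)
  )
  writeLines(summary_lines, p("summary.txt"))
  invisible(out_dir)
}

window_lines <- function(label, windows) {
  if (nrow(windows) == 0) return(sprintf("  %s: none", label))
  sprintf("  %s: %s", label,
          paste(sprintf("%.1f-%.1f (%s)", windows$from_age, windows$to_age,
                        windows$direction), collapse = ", "))
}

plot_band_pdf <- function(band, path) {
  yvar <- if ("derivative" %in% names(band)) "derivative" else "difference"
  g <- ggplot2::ggplot(tibble::as_tibble(band), ggplot2::aes(x = .data$age)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
                         alpha = 0.3) +
    ggplot2::geom_line(ggplot2::aes(y = .data[[yvar]])) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "age (years)", y = yvar) +
    ggplot2::theme_minimal()
  ggplot2::ggsave(path, g, width = 6, height = 4, device = grDevices::pdf)
  invisible(path)
}
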