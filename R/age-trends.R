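# Nonlinear age-trend inference: penalized-spline smooths per condition with
# dyad-nested random intercepts, first-derivative simultaneous confidence
# bands, significant age windows, condition-difference smooths, and a
# Beta-family model for earnings proportions.

#' Fit a penalized-spline age smooth per condition
#'
#' Fits, with `mgcv::gam()`, `dv ~ condition + s(age, by = condition)` (one
#' cubic regression spline per condition level; a single smooth when only
#' one condition is present), plus random intercepts for dyad and for
#' participant within dyad, with smoothing parameters selected by restricted
#' maximum likelihood. The participant intercept is dropped automatically
#' (with a message) when no participant contributes more than one row, since
#' it would then be confounded with the residual.
#'
#' @param table Data frame with columns `age`, the dependent variable, and
#'   (optionally) `condition`, `dyad_id`, `participant_id`.
#' @param dv Name of the dependent-variable column.
#' @param k Basis dimension per smooth (default 10).
#' @param bs Spline basis (default `"cr"`, cubic regression).
#' @param family A `family` object (Gaussian default; see
#'   [fit_proportion_model()] for the Beta family).
#' @param random Character subset of `c("dyad", "participant")`, or `NULL`
#'   for automatic selection based on the columns present.
#' @param method Smoothing-parameter criterion (default `"REML"`).
#' @return An object of class `age_smooth` wrapping the fitted `gam`; see
#'   [smooth_terms()] and [parametric_terms()] for the edf/F and B/SE/t (or
#'   z) tables.
#' @export
fit_age_smooth <- function(table, dv, k = 10, bs = "cr",
                           family = stats::gaussian(), random = NULL,
                           method = "REML") {
  stopifnot(is.data.frame(table), dv %in% names(table), "age" %in% names(table))
  dd <- data.frame(age = as.numeric(table$age), .dv = as.numeric(table[[dv]]))
  if (anyNA(dd)) stop("`age` and `", dv, "` must not contain missing values")
  n_ages <- length(unique(dd$age))
  if (n_ages < k + 1) {
    stop("only ", n_ages, " distinct ages but the smooth basis needs more; ",
         "lower `k` (currently ", k, ") or supply more distinct ages")
  }
  has_cond <- "condition" %in% names(table) && length(unique(table$condition)) > 1
  if ("condition" %in% names(table)) {
    dd$condition <- factor(table$condition)
  }
  auto_random <- is.null(random)
  if (auto_random) {
    random <- character(0)
    if ("dyad_id" %in% names(table) && any(table(table$dyad_id) > 1)) {
      random <- c(random, "dyad")
    }
    if ("participant_id" %in% names(table)) {
      if (any(table(table$participant_id) > 1)) {
        random <- c(random, "participant")
      } else if (!"dyad_id" %in% names(table)) {
        message("no participant has more than one row; ",
                "participant random intercept omitted")
      }
    }
    # keep the model comfortably below saturation: drop the finest random
    # term while the coefficient count approaches the sample size
    n_cond <- if (has_cond) length(unique(table$condition)) else 1
    repeat {
      n_coef <- 1 + (n_cond - 1) + n_cond * (k - 1) +
        ("dyad" %in% random) * length(unique(table$dyad_id)) +
        ("participant" %in% random) * length(unique(table$participant_id))
      if (nrow(dd) >= n_coef + 10 || length(random) == 0) break
      dropped <- random[length(random)]
      random <- random[-length(random)]
      message("too few rows (", nrow(dd), ") for a ", dropped,
              " random intercept; dropping it")
    }
  }
  if ("dyad" %in% random) dd$dyad_id <- factor(table$dyad_id)
  if ("participant" %in% random) dd$participant_id <- factor(table$participant_id)

  rhs <- if (has_cond) {
    sprintf("condition + s(age, by = condition, k = %d, bs = '%s')", k, bs)
  } else {
    sprintf("s(age, k = %d, bs = '%s')", k, bs)
  }
  if ("dyad" %in% random) rhs <- paste0(rhs, " + s(dyad_id, bs = 're')")
  if ("participant" %in% random) rhs <- paste0(rhs, " + s(participant_id, bs = 're')")
  form <- stats::as.formula(paste(".dv ~", rhs))
  g <- mgcv::gam(form, data = dd, family = family, method = method)
  structure(list(
    gam = g,
    dv = dv,
    data = dd,
    conditions = if (has_cond || "condition" %in% names(dd)) levels(dd$condition) else NULL,
    age_range = range(dd$age),
    k = k,
    random = random,
    squeezed = FALSE
  ), class = "age_smooth")
}

#' @export
print.age_smooth <- function(x, ...) {
  cat(sprintf("Age smooth for '%s' (%s family, %d rows)\n", x$dv,
              x$gam$family$family, nrow(x$data)))
  if (!is.null(x$conditions)) {
    cat("  conditions:", paste(x$conditions, collapse = ", "), "\n")
  }
  if (isTRUE(x$squeezed)) cat("  boundary proportions squeezed before fitting\n")
  cat("Smooth terms:\n")
  print(round(smooth_terms(x, as_matrix = TRUE), 4))
  cat("Parametric terms:\n")
  print(round(parametric_terms(x, as_matrix = TRUE), 4))
  invisible(x)
}

#' Smooth-term and parametric-term summaries of an age smooth
#'
#' `smooth_terms()` returns the effective degrees of freedom and test
#' statistic per smooth; `parametric_terms()` the coefficient table
#' (estimate `B`, `SE`, t or z statistic, p) for the parametric part,
#' including condition offsets.
#'
#' @param fit An [fit_age_smooth()] object.
#' @param as_matrix Return the raw summary matrix instead of a tibble.
#' @return A tibble (or matrix) of term statistics.
#' @export
smooth_terms <- function(fit, as_matrix = FALSE) {
  stopifnot(inherits(fit, "age_smooth"))
  s <- summary(fit$gam)$s.table
  if (as_matrix) return(s)
  tibble::as_tibble(s, rownames = "term")
}

#' @rdname smooth_terms
#' @export
parametric_terms <- function(fit, as_matrix = FALSE) {
  stopifnot(inherits(fit, "age_smooth"))
  p <- summary(fit$gam)$p.table
  if (as_matrix) return(p)
  out <- tibble::as_tibble(p, rownames = "term")
  names(out) <- c("term", "B", "SE", "statistic", "p")
  out
}

# Linear-predictor design matrix at given ages for one condition level, with
# the random-intercept columns zeroed so predictions are population-level.
age_lp_matrix <- function(fit, ages, condition = NULL) {
  dd <- fit$data
  nd <- data.frame(age = ages)
  if (!is.null(fit$conditions)) {
    lev <- if (is.null(condition)) fit$conditions[1] else condition
    if (!lev %in% fit$conditions) {
      stop("condition '", lev, "' is not a level of this fit (",
           paste(fit$conditions, collapse = ", "), ")")
    }
    nd$condition <- factor(lev, levels = fit$conditions)
  }
  if ("dyad_id" %in% names(dd)) nd$dyad_id <- factor(levels(dd$dyad_id)[1], levels(dd$dyad_id))
  if ("participant_id" %in% names(dd)) {
    nd$participant_id <- factor(levels(dd$participant_id)[1], levels(dd$participant_id))
  }
  Xp <- stats::predict(fit$gam, nd, type = "lpmatrix")
  for (sm in fit$gam$smooth) {
    if (inherits(sm, "random.effect")) {
      Xp[, sm$first.para:sm$last.para] <- 0
    }
  }
  Xp
}

# Simultaneous critical multiplier: draw coefficient vectors from the
# approximate Gaussian posterior, take the `level` quantile of the maximum
# absolute standardized deviation across evaluation points.
simultaneous_crit <- function(Xd, V, se, n_draws, level, seed) {
  ev <- eigen(V, symmetric = TRUE, only.values = TRUE)$values
  if (any(!is.finite(ev)) || min(ev) < -1e-6 * max(abs(ev))) {
    stop("coefficient covariance is singular; cannot form a simultaneous band")
  }
  state <- local_rng_state(seed)
  on.exit(restore_rng_state(state), add = TRUE)
  B <- MASS::mvrnorm(n_draws, mu = rep(0, ncol(V)), Sigma = V, tol = 1e-6)
  dev <- abs(Xd %*% t(B)) / se
  maxdev <- apply(dev, 2, max)
  stats::quantile(maxdev, probs = level, names = FALSE, type = 8)
}

#' Population-level fitted age curve
#'
#' The fitted smooth (plus parametric offsets) for one condition level at the
#' given ages, with random intercepts excluded; the curve whose derivative
#' [derivative_simultaneous_band()] evaluates. On the link scale for
#' non-Gaussian families.
#'
#' @param fit An [fit_age_smooth()] object.
#' @param ages Evaluation ages (default: 100 points over the observed range).
#' @param condition Condition level (default: first level / single smooth).
#' @return A tibble: `age`, `estimate`, `se`.
#' @export
smooth_estimate <- function(fit, ages = NULL, condition = NULL) {
  stopifnot(inherits(fit, "age_smooth"))
  if (is.null(ages)) {
    ages <- seq(fit$age_range[1], fit$age_range[2], length.out = 100)
  }
  Xp <- age_lp_matrix(fit, ages, condition)
  V <- stats::vcov(fit$gam)
  tibble::tibble(age = ages,
                 estimate = drop(Xp %*% stats::coef(fit$gam)),
                 se = sqrt(rowSums((Xp %*% V) * Xp)))
}

#' Simultaneous confidence band for the first derivative of an age smooth
#'
#' Evaluates the central finite-difference first derivative of the fitted
#' age curve at `n_points` ages spanning the observed range, with a
#' simultaneous band: pointwise standard errors are widened by the `level`
#' quantile of the maximum absolute standardized deviation over draws from
#' the approximate Gaussian posterior of the coefficients, so the band's
#' joint coverage over all points is `level`.
#'
#' @param fit An [fit_age_smooth()] object.
#' @param condition Condition level whose smooth to differentiate (default:
#'   first level, or the single smooth).
#' @param n_points Number of evaluation ages (default 100).
#' @param n_draws Posterior draws for the simultaneous multiplier (default
#'   10000).
#' @param level Joint coverage level (default 0.95).
#' @param seed Seed for the posterior draws.
#' @return A tibble of class `derivative_band`: `age`, `derivative`, `se`,
#'   `lower`, `upper`, with the critical multiplier, level and condition as
#'   attributes. On the link scale for non-Gaussian families.
#' @export
derivative_simultaneous_band <- function(fit, condition = NULL, n_points = 100,
                                         n_draws = 10000, level = 0.95,
                                         seed = 1L) {
  stopifnot(inherits(fit, "age_smooth"), n_points >= 2, n_draws >= 100)
  ages <- seq(fit$age_range[1], fit$age_range[2], length.out = n_points)
  h <- 1e-4 * diff(fit$age_range)
  X1 <- age_lp_matrix(fit, ages - h, condition)
  X2 <- age_lp_matrix(fit, ages + h, condition)
  Xd <- (X2 - X1) / (2 * h)
  beta <- stats::coef(fit$gam)
  V <- stats::vcov(fit$gam)
  est <- drop(Xd %*% beta)
  se <- pmax(sqrt(rowSums((Xd %*% V) * Xd)), 1e-12)
  crit <- simultaneous_crit(Xd, V, se, n_draws, level, seed)
  out <- tibble::tibble(age = ages, derivative = est, se = se,
                        lower = est - crit * se, upper = est + crit * se)
  structure(out, class = c("derivative_band", class(out)),
            crit = crit, level = level,
            condition = condition %||% (fit$conditions[1] %||% "(all)"),
            dv = fit$dv)
}

#' Age windows where a simultaneous band excludes zero
#'
#' Maximal contiguous runs of evaluation points whose interval lies entirely
#' above or below zero: the ages at which the derivative (or condition
#' difference) is significant at the band's joint level.
#'
#' @param band A [derivative_simultaneous_band()] or [difference_smooth()]
#'   result, or any data frame with `age`, `lower`, `upper` columns.
#' @return A tibble with one row per window: `from_age`, `to_age`,
#'   `direction` (`"positive"`/`"negative"`), `n_points`.
#' @export
significant_windows <- function(band) {
  stopifnot(is.data.frame(band), all(c("age", "lower", "upper") %in% names(band)))
  excl <- band$lower > 0 | band$upper < 0
  runs <- rle(excl)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  keep <- which(runs$values)
  tibble::tibble(
    from_age = band$age[starts[keep]],
    to_age = band$age[ends[keep]],
    direction = vapply(keep, function(i) {
      if (band$lower[starts[i]] > 0) "positive" else "negative"
    }, character(1)),
    n_points = runs$lengths[keep]
  )
}

#' Difference of condition smooths with a simultaneous band
#'
#' Pointwise difference between the fitted curves (smooth plus parametric
#' condition offset, random intercepts excluded) of two condition levels at
#' `n_points` ages, with a simultaneous confidence band constructed as in
#' [derivative_simultaneous_band()]. Age bands where the band excludes zero
#' mark significant condition differences.
#'
#' @inheritParams derivative_simultaneous_band
#' @param condition_a,condition_b Condition levels to contrast (a minus b).
#' @return A tibble of class `difference_band`: `age`, `difference`, `se`,
#'   `lower`, `upper`, with attributes as for the derivative band. On the
#'   link scale for non-Gaussian families.
#' @export
difference_smooth <- function(fit, condition_a, condition_b, n_points = 100,
                              n_draws = 10000, level = 0.95, seed = 1L) {
  stopifnot(inherits(fit, "age_smooth"))
  if (is.null(fit$conditions)) stop("fit has no condition factor to contrast")
  ages <- seq(fit$age_range[1], fit$age_range[2], length.out = n_points)
  Xd <- age_lp_matrix(fit, ages, condition_a) - age_lp_matrix(fit, ages, condition_b)
  beta <- stats::coef(fit$gam)
  V <- stats::vcov(fit$gam)
  est <- drop(Xd %*% beta)
  se <- pmax(sqrt(rowSums((Xd %*% V) * Xd)), 1e-12)
  crit <- if (all(abs(Xd) < 1e-12)) 0 else simultaneous_crit(Xd, V, se, n_draws, level, seed)
  out <- tibble::tibble(age = ages, difference = est, se = se,
                        lower = est - crit * se, upper = est + crit * se)
  structure(out, class = c("difference_band", class(out)),
            crit = crit, level = level,
            pair = c(condition_a, condition_b), dv = fit$dv)
}

#' Beta-family age smooth for proportion outcomes
#'
#' Same predictor structure as [fit_age_smooth()] but with a Beta likelihood
#' and logit link, for dependent variables that are proportions (earnings as
#' a share of the maximum possible). The Beta family excludes the
#' boundaries, so if any value sits at 0 or 1 the standard squeeze
#' `(y * (n - 1) + 0.5) / n` is applied first and recorded in the result.
#' Parametric test statistics are z values; bands are on the logit scale.
#'
#' @inheritParams fit_age_smooth
#' @return An `age_smooth` object with `squeezed` set accordingly.
#' @export
fit_proportion_model <- function(table, dv, k = 10, bs = "cr", random = NULL,
                                 method = "REML") {
  stopifnot(is.data.frame(table), dv %in% names(table))
  y <- table[[dv]]
  if (any(y < 0 | y > 1, na.rm = TRUE)) {
    stop("`", dv, "` must lie in [0, 1] to be modeled as a proportion")
  }
  squeezed <- any(y <= 0 | y >= 1, na.rm = TRUE)
  if (squeezed) {
    n <- sum(!is.na(y))
    table[[dv]] <- (y * (n - 1) + 0.5) / n
  }
  fit <- fit_age_smooth(table, dv, k = k, bs = bs,
                        family = mgcv::betar(link = "logit"),
                        random = random, method = method)
  fit$squeezed <- squeezed
  fit
}

`%||%` <- function(a, b) if (is.null(a)) b else a
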