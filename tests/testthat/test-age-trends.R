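# Penalized-spline age smooths, derivative and difference simultaneous bands.

test_that("a constant outcome yields a flat smooth and an all-covering band", {
  tab <- make_age_table(32, f = function(a) 0.5 + 0 * a, sd = 0.1, seed = 1)
  fit <- fit_age_smooth(tab, "y")
  expect_lt(smooth_terms(fit)$edf[1], 1.6)
  band <- derivative_simultaneous_band(fit, n_draws = 2000, seed = 1)
  expect_equal(nrow(band), 100)
  expect_true(all(band$lower <= 0 & band$upper >= 0))
  expect_lt(max(abs(band$derivative)), 0.05)
  expect_equal(nrow(significant_windows(band)), 0)
})

test_that("a linear age trend is recovered with its slope", {
  tab <- make_age_table(48, f = function(a) 0.1 * a, sd = 0.05, seed = 2)
  fit <- fit_age_smooth(tab, "y")
  band <- derivative_simultaneous_band(fit, n_draws = 2000, seed = 2)
  expect_equal(mean(band$derivative), 0.1, tolerance = 0.1)
  expect_true(all(abs(band$derivative - 0.1) < 0.05))
  # slope this strong is detected over most of the range
  expect_gt(mean(band$lower > 0), 0.7)
  win <- significant_windows(band)
  expect_gt(nrow(win), 0)
  expect_true(all(win$direction == "positive"))
  # the simultaneous band is at least as wide as the pointwise one
  expect_gte(attr(band, "crit"), stats::qnorm(0.975))
})

test_that("the derivative integrates back to the fitted curve", {
  tab <- make_age_table(40, f = function(a) 0.3 * sin(a / 2) + 0.05 * a,
                        sd = 0.05, seed = 3)
  fit <- fit_age_smooth(tab, "y")
  band <- derivative_simultaneous_band(fit, n_draws = 500, seed = 3)
  est <- smooth_estimate(fit, band$age)
  dx <- diff(band$age)
  recon <- est$estimate[1] +
    c(0, cumsum((band$derivative[-1] + band$derivative[-100]) / 2 * dx))
  err <- max(abs(recon - est$estimate))
  expect_lt(err, 0.01 * diff(range(est$estimate)))
})

test_that("smooth fitting guards its inputs", {
  tab <- make_age_table(32, seed = 4)
  expect_error(fit_age_smooth(tab, "nope"))
  few <- tab[1:8, ]
  expect_error(fit_age_smooth(few, "y"), "distinct ages")
  expect_error(fit_age_smooth(few, "y", k = 4), NA)
})

test_that("difference smooth is zero against itself and antisymmetric", {
  tab <- make_age_table(24, f = function(a) 0.02 * a, sd = 0.1, seed = 5,
                        conditions = c("A", "B"))
  fit <- fit_age_smooth(tab, "y")
  self_diff <- difference_smooth(fit, "A", "A", n_draws = 500, seed = 5)
  expect_true(all(abs(self_diff$difference) < 1e-10))
  expect_true(all(self_diff$lower <= 0 & self_diff$upper >= 0))
  ab <- difference_smooth(fit, "A", "B", n_draws = 500, seed = 6)
  ba <- difference_smooth(fit, "B", "A", n_draws = 500, seed = 6)
  expect_equal(ab$difference, -ba$difference, tolerance = 1e-12)
  expect_error(difference_smooth(fit, "A", "C"), "not a level")
})

test_that("an injected condition offset at young ages is localized by the band", {
  f_shift <- function(a) 0.25 * pmax(0, (15 - a) / 3)
  tab_a <- make_age_table(48, f = function(a) 0.5 + 0 * a, sd = 0.08, seed = 7,
                          conditions = "Base")
  tab_b <- make_age_table(48, f = function(a) 0.5 + f_shift(a), sd = 0.08,
                          seed = 8, conditions = "Shift")
  tab <- dplyr::bind_rows(tab_a, tab_b)
  fit <- fit_age_smooth(tab, "y")
  band <- difference_smooth(fit, "Shift", "Base", n_draws = 2000, seed = 7)
  win <- significant_windows(band)
  expect_gt(nrow(win), 0)
  expect_true(all(win$direction == "positive"))
  # detection confined to the young end where the offset lives
  expect_true(all(win$to_age < 17))
  expect_lt(win$from_age[1], 14)
})

test_that("significant windows are read off the band exactly", {
  band <- tibble::tibble(age = seq(12, 22, length.out = 50),
                         lower = rep(-1, 50), upper = rep(1, 50))
  expect_equal(nrow(significant_windows(band)), 0)
  band$lower[10:30] <- 0.2
  band$upper[10:30] <- 0.6
  win <- significant_windows(band)
  expect_equal(nrow(win), 1)
  expect_equal(win$from_age, band$age[10])
  expect_equal(win$to_age, band$age[30])
  expect_equal(win$direction, "positive")
  expect_equal(win$n_points, 21L)
})

test_that("simultaneous bands match a parametric-bootstrap oracle on a small fixture", {
  # 40 observations, no random intercepts, 500 bootstrap refits
  tab <- make_age_table(20, f = function(a) 0.08 * a, sd = 0.1, seed = 9)
  tab$dyad_id <- NULL
  tab$participant_id <- NULL
  fit <- fit_age_smooth(tab, "y", random = character(0))
  band <- derivative_simultaneous_band(fit, n_draws = 4000, seed = 9)

  g <- fit$gam
  sigma <- sqrt(g$sig2)
  mu <- stats::fitted(g)
  ages <- band$age
  boot_stat <- withr::with_seed(10, vapply(1:500, function(b) {
    tb <- tab
    tb$y <- mu + stats::rnorm(length(mu), 0, sigma)
    fb <- fit_age_smooth(tb, "y", random = character(0))
    h <- 1e-4 * diff(fit$age_range)
    db <- (smooth_estimate(fb, ages + h)$estimate -
             smooth_estimate(fb, ages - h)$estimate) / (2 * h)
    max(abs(db - band$derivative) / band$se)
  }, numeric(1)))
  crit_boot <- stats::quantile(boot_stat, 0.95, names = FALSE)
  crit_sim <- attr(band, "crit")
  # critical multipliers agree to within a modest factor...
  expect_lt(abs(crit_boot - crit_sim) / crit_sim, 0.3)
  # ...and the resulting significance calls coincide at nearly every age
  excl_sim <- band$lower > 0 | band$upper < 0
  excl_boot <- (band$derivative - crit_boot * band$se) > 0 |
    (band$derivative + crit_boot * band$se) < 0
  expect_gt(mean(excl_sim == excl_boot), 0.95)
})

test_that("proportion outcomes get a Beta-family fit with boundary squeezing", {
  tab <- make_age_table(32, f = function(a) 0.9 + 0 * a, sd = 0.03, seed = 11)
  tab$y <- pmin(tab$y, 1)
  tab$y[1] <- 1 # force a boundary value
  fit <- fit_proportion_model(tab, "y")
  expect_true(fit$squeezed)
  expect_true(all(fit$data$.dv > 0 & fit$data$.dv < 1))
  expect_match(fit$gam$family$family, "Beta")
  bad <- tab
  bad$y[2] <- 1.4
  expect_error(fit_proportion_model(bad, "y"), "proportion")

  # a true mean difference between conditions shows up with a negative sign
  pa <- make_age_table(40, f = function(a) 0.92 + 0 * a, sd = 0.03, seed = 12,
                       conditions = "Base")
  pb <- make_age_table(40, f = function(a) 0.79 + 0 * a, sd = 0.05, seed = 13,
                       conditions = "Opp")
  both <- dplyr::bind_rows(pa, pb)
  both$y <- pmin(pmax(both$y, 0.01), 0.99)
  pfit <- fit_proportion_model(both, "y")
  expect_false(pfit$squeezed)
  pt <- parametric_terms(pfit)
  row <- pt[grepl("Opp", pt$term), ]
  expect_lt(row$B, 0) # z-scale coefficient: Opp earns less
  expect_lt(row$p, 0.05)
})
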