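# Model-free behavioral measures per participant x condition.

#' Proportion of risky choices
#'
#' Number of risky options chosen divided by the number of trials in the
#' record set. Coarser than the fitted risk exponent (it ignores the relative
#' utilities on each trial) but free of model-based exclusions.
#'
#' @param records Choice records with a logical `chose_risky` column.
#' @return A proportion in \[0, 1\].
#' @export
proportion_risky <- function(records) {
  stopifnot(is.data.frame(records))
  if (nrow(records) == 0) stop("no choice records")
  mean(as.logical(records$chose_risky))
}

#' Simulated earnings of a choice vector
#'
#' Sum of the expected value of each selected option: `p_win * amount` when
#' the risky option was chosen, the safe amount otherwise. The measure is
#' defined on expected values; no lottery outcomes are sampled.
#'
#' @inheritParams proportion_risky
#' @return Total earnings in dollars.
#' @export
simulated_earnings <- function(records) {
  stopifnot(is.data.frame(records))
  if (nrow(records) == 0) stop("no choice records")
  chose <- as.logical(records$chose_risky)
  sum(ifelse(chose, records$p_win * records$amount, records$safe_amount))
}

#' Earnings as a proportion of the maximum possible
#'
#' [simulated_earnings()] divided by [max_possible_earnings()] of the choice
#' set the records came from; the dependent variable of the Beta-family
#' earnings models.
#'
#' @inheritParams proportion_risky
#' @param set Optional choice set the records are aligned with; defaults to
#'   the records themselves (which carry the same trial columns). When given,
#'   the trial grids must match.
#' @return A proportion in (0, 1\].
#' @export
earnings_proportion <- function(records, set = NULL) {
  stopifnot(is.data.frame(records))
  if (nrow(records) == 0) stop("no choice records")
  if (is.null(set)) set <- records
  same_grid <- nrow(set) == nrow(records) &&
    identical(sort_grid(set), sort_grid(records))
  if (!same_grid) stop("records are not aligned with the supplied choice set")
  simulated_earnings(records) / max_possible_earnings(set)
}

sort_grid <- function(d) {
  g <- data.frame(p_win = d$p_win, amount = d$amount, safe_amount = d$safe_amount)
  g <- g[order(g$p_win, g$amount), , drop = FALSE]
  rownames(g) <- NULL
  g
}

#' Behavioral summary for one participant x condition
#'
#' @inheritParams earnings_proportion
#' @param participant_id,condition Labels carried into the row.
#' @return A one-row tibble: `participant_id`, `condition`, `prop_risky`,
#'   `earnings`, `earnings_prop`.
#' @export
behavior_summary <- function(records, set = NULL,
                             participant_id = NA_character_,
                             condition = NA_character_) {
  tibble::tibble(
    participant_id = participant_id,
    condition = condition,
    prop_risky = proportion_risky(records),
    earnings = simulated_earnings(records),
    earnings_prop = earnings_proportion(records, set)
  )
}
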