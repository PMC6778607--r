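#' Cost of one round
#'
#' The money spent searching in a round: unique opened cells times the
#' cell cost plus elapsed time steps times the step cost (information
#' cost + time pressure).
#'
#' @param record An `mlq_round_record`.
#' @param config A [game_config()].
#' @return Cost in IRR.
#' @examples
#' # 4 cells and 3 ticks under the default economy: 4*450 + 3*780 = 4140
#' @export
round_cost <- function(record, config) {
  validate_game_config(config)
  n_open <- nrow(unique(record$opened_cells))
  n_open * config$cell_cost + record$ticks * config$step_cost
}

trace_round_costs <- function(trace) {
  vapply(trace$rounds, function(r) as.numeric(r$cost), numeric(1))
}

#' Expected value of a session
#'
#' The sum over all rounds of the per-round allocation minus that round's
#' search cost: the credit the subject would have banked had every choice
#' been correct. This is the gain ceiling their search behaviour set; it
#' can be zero or negative if search spending matched or exceeded the
#' allocations. (Some of the literature calls this same quantity
#' "expected utility"; this package standardizes on *expected value*.)
#'
#' @param trace A [subject_trace()].
#' @return Expected value in IRR.
#' @examples
#' # two rounds costing 4140 and 6600: (15000-4140) + (15000-6600) = 19260
#' @export
expected_value <- function(trace) {
  validate_trace(trace)
  sum(trace$config$round_allocation - trace_round_costs(trace))
}

#' Cost of incorrect choices
#'
#' The reward forgone on wrong and no-response rounds: the remaining
#' allocation (`round_allocation - cost`, floored at zero) summed over
#' every round not answered correctly. A no-response round forfeits its
#' remainder exactly like a wrong one.
#'
#' @param trace A [subject_trace()].
#' @return Forgone reward in IRR (non-negative).
#' @export
incorrect_choice_cost <- function(trace) {
  validate_trace(trace)
  alloc <- trace$config$round_allocation
  sum(vapply(trace$rounds, function(r) {
    if (isTRUE(r$correct)) 0 else max(0, alloc - r$cost)
  }, numeric(1)))
}

#' Utility (net profit) of a session
#'
#' Expected value minus the cost of incorrect choices: the net profit
#' actually realized over the session. When no round's cost exceeds its
#' allocation this equals the sum over correct rounds of
#' `round_allocation - cost`, i.e. exactly what the ledger banked.
#'
#' @param trace A [subject_trace()].
#' @return Utility in IRR.
#' @export
utility <- function(trace) {
  expected_value(trace) - incorrect_choice_cost(trace)
}

#' The choice-quality index
#'
#' `utility / expected_value x 100`: the percentage of the achievable net
#' gains (given the search costs actually incurred) that the subject's
#' choices realized. 100 means every round with a positive remaining
#' allocation was answered correctly; 0 means none was. The index is
#' undefined when expected value is not positive, and this function then
#' raises an error rather than returning a number.
#'
#' Because both numerator and denominator are sums of monetary amounts,
#' the index is invariant to rescaling all monetary constants by a common
#' positive factor.
#'
#' @param trace A [subject_trace()].
#' @return Choice quality in percent.
#' @examples
#' # two rounds netting 10860 (correct) and 8400 (forfeited):
#' # 10860 / 19260 * 100 = 56.39%
#' @export
choice_quality <- function(trace) {
  ev <- expected_value(trace)
  if (ev <= 0) {
    stop("choice quality is undefined: expected value is ", ev,
         " (must be positive)")
  }
  utility(trace) / ev * 100
}

#' Search statistics of a session
#'
#' @param trace A [subject_trace()].
#' @return A list with `opened_total` (unique cells bought over the
#'   session), `opened_fraction` (share of all available cells,
#'   `opened_total / (n_rounds x n_alternatives x n_attributes)`), and
#'   `opened_per_round_mean`.
#' @export
search_stats <- function(trace) {
  validate_trace(trace)
  cfg <- trace$config
  opened_total <- sum(vapply(trace$rounds,
                             function(r) nrow(unique(r$opened_cells)), integer(1)))
  available <- cfg$n_rounds * cfg$n_alternatives * cfg$n_attributes
  list(opened_total = opened_total,
       opened_fraction = opened_total / available,
       opened_per_round_mean = opened_total / cfg$n_rounds)
}

#' Accuracy statistics of a session
#'
#' @param trace A [subject_trace()].
#' @return A list with `n_correct`, `n_wrong`, `n_noresponse` (rounds
#'   ended with no choice; counted separately, though they forfeit like
#'   wrong rounds) and `correct_pct` (`n_correct / n_rounds x 100`).
#' @export
accuracy_stats <- function(trace) {
  validate_trace(trace)
  chosen <- vapply(trace$rounds, function(r) !is.na(r$chosen), logical(1))
  correct <- vapply(trace$rounds, function(r) isTRUE(r$correct), logical(1))
  n_correct <- sum(correct)
  n_noresponse <- sum(!chosen)
  n_wrong <- sum(chosen & !correct)
  list(n_correct = n_correct, n_wrong = n_wrong, n_noresponse = n_noresponse,
       correct_pct = n_correct / trace$config$n_rounds * 100)
}

#' Fraction of available cells opened, as a percentage
#'
#' The summary used for a cohort's search-depth row: opened boxes over all
#' available boxes. Accepts a (possibly fractional, e.g. cohort-mean)
#' count of opened boxes.
#'
#' @param opened_total Number of boxes opened over a session (may be a
#'   cohort mean).
#' @param config A [game_config()].
#' @return Percentage of available cells.
#' @examples
#' search_fraction_pct(407.35, game_config())  # 42.43229...
#' @export
search_fraction_pct <- function(opened_total, config) {
  validate_game_config(config)
  opened_total / (config$n_rounds * config$n_alternatives * config$n_attributes) * 100
}

#' Correct choices as a percentage of rounds
#'
#' @param n_correct Number of correct rounds (may be a cohort mean).
#' @param config A [game_config()].
#' @return Percentage correct.
#' @examples
#' accuracy_pct(46.11, game_config())  # 76.85
#' @export
accuracy_pct <- function(n_correct, config) {
  validate_game_config(config)
  n_correct / config$n_rounds * 100
}

#' All per-subject metrics at once
#'
#' Computes the full per-subject summary a cohort analysis needs: search
#' and accuracy statistics, the cost decomposition (information cost vs
#' time cost), expected value, incorrect-choice cost, utility, and the
#' choice-quality index. If expected value is not positive the index is
#' `NA` with a warning (the error from [choice_quality()] is reserved for
#' direct calls).
#'
#' @param trace A [subject_trace()].
#' @return A one-row data.frame; see [cohort_metrics()] for the cohort
#'   version.
#' @export
subject_metrics <- function(trace) {
  validate_trace(trace)
  cfg <- trace$config
  ss <- search_stats(trace)
  as_ <- accuracy_stats(trace)
  info_cost <- ss$opened_total * cfg$cell_cost
  ticks_total <- sum(vapply(trace$rounds, function(r) r$ticks, integer(1)))
  ev <- expected_value(trace)
  icc <- incorrect_choice_cost(trace)
  cq <- if (ev > 0) (ev - icc) / ev * 100 else {
    warning("expected value not positive for subject ", trace$subject_id,
            "; choice quality set to NA")
    NA_real_
  }
  data.frame(
    subject_id = trace$subject_id,
    opened_total = ss$opened_total,
    opened_fraction = ss$opened_fraction,
    opened_per_round_mean = ss$opened_per_round_mean,
    n_correct = as_$n_correct,
    n_wrong = as_$n_wrong,
    n_noresponse = as_$n_noresponse,
    correct_pct = as_$correct_pct,
    information_cost = info_cost,
    time_cost = ticks_total * cfg$step_cost,
    expected_value = ev,
    incorrect_choice_cost = icc,
    utility = ev - icc,
    choice_quality = cq,
    stringsAsFactors = FALSE
  )
}

#' Per-subject metrics for a whole cohort
#'
#' @param traces List of [subject_trace()]s.
#' @return A data.frame, one row per subject (see [subject_metrics()]).
#' @export
cohort_metrics <- function(traces) {
  if (!is.list(traces) || length(traces) == 0) {
    stop("traces must be a non-empty list of subject traces")
  }
  do.call(rbind, lapply(traces, subject_metrics))
}
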