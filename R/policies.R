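#' Synthetic agent policies
#'
#' A policy is a rule for playing one round: which cells to buy, in what
#' order, and when to commit to an alternative. The five kinds cover the
#' classic families of multi-attribute choice strategies:
#'
#' * `random` -- buys nothing and guesses uniformly (the chance baseline;
#'   correct with probability `1 / n_alternatives`).
#' * `exhaustive` -- buys every cell (column-major) and picks the row with
#'   the most criterion matches; error-free, it is always correct.
#' * `take_the_best` -- lexicographic cue use: inspects attributes in a
#'   priority order, one full column at a time over the surviving
#'   candidates, keeps the candidates matching the criterion on that cue,
#'   and stops as soon as a single candidate leads.
#' * `satisficing` -- scans alternatives in order and commits to the first
#'   whose inspected attributes reach an aspiration threshold of matches;
#'   it skips an alternative early once the threshold is out of reach.
#' * `weighted_additive` -- buys everything and scores rows by a weighted
#'   sum of criterion matches (compensatory strategy).
#'
#' All kinds support `error_rate`: at the moment of choice, with this
#' probability the agent commits to a uniformly drawn *other* alternative
#' instead of its intended one (decision noise, moving accuracy
#' continuously between ceiling and chance). `ticks_per_action` is the
#' number of time steps each cell purchase consumes; committing to a
#' choice always consumes one further tick. `spend_target` models
#' deliberation under the time-pressure channel: once the agent has
#' decided, it keeps letting time steps elapse until the round's accrued
#' cost approaches the target (never past it), so per-round spending is
#' governed by time use rather than search depth alone. `noresponse_rate`
#' is the per-round probability that the agent freezes and lets the round
#' lapse with no choice (deliberation time still elapses; the remaining
#' allocation is forfeited).
#'
#' @param kind One of `"random"`, `"exhaustive"`, `"take_the_best"`,
#'   `"satisficing"`, `"weighted_additive"`.
#' @param error_rate Probability in `[0, 1]` of a noisy choice.
#' @param ticks_per_action Time steps charged per cell purchase (>= 0).
#' @param spend_target Deliberation budget in IRR per round (`NA` for
#'   none): idle time steps are appended until the round's cost is within
#'   one step cost of this target.
#' @param noresponse_rate Probability in `[0, 1]` of letting a round lapse.
#' @param priority Attribute inspection order for `take_the_best`
#'   (a permutation of `1:n_attributes`; default natural order).
#' @param threshold Aspiration level for `satisficing`: the number of
#'   matching attributes that suffices (default 3).
#' @param weights Attribute weights for `weighted_additive` (default
#'   decreasing `n_attributes:1`).
#' @return An object of class `mlq_policy`.
#' @examples
#' policy("take_the_best", priority = c(2, 1, 3, 4), error_rate = 0.1)
#' @export
policy <- function(kind = c("random", "exhaustive", "take_the_best",
                            "satisficing", "weighted_additive"),
                   error_rate = 0, ticks_per_action = 1L,
                   spend_target = NA_real_, noresponse_rate = 0,
                   priority = NULL, threshold = 3L, weights = NULL) {
  kind <- match.arg(kind)
  if (error_rate < 0 || error_rate > 1) stop("error_rate must be in [0, 1]")
  if (noresponse_rate < 0 || noresponse_rate > 1) {
    stop("noresponse_rate must be in [0, 1]")
  }
  if (ticks_per_action < 0) stop("ticks_per_action must be >= 0")
  if (!is.na(spend_target) && spend_target < 0) {
    stop("spend_target must be >= 0 (or NA for none)")
  }
  if (threshold < 0) stop("satisficing threshold must be >= 0")
  p <- list(kind = kind, error_rate = error_rate,
            ticks_per_action = as.integer(ticks_per_action),
            spend_target = as.numeric(spend_target),
            noresponse_rate = noresponse_rate,
            priority = priority, threshold = as.integer(threshold),
            weights = weights)
  class(p) <- "mlq_policy"
  p
}

#' @export
print.mlq_policy <- function(x, ...) {
  cat(sprintf("<mlq_policy> %s (error_rate %.2f, ticks/action %d)\n",
              x$kind, x$error_rate, x$ticks_per_action))
  invisible(x)
}

#' The agent's view of a round in progress
#'
#' What a policy is allowed to see: the criterion (the preference profile
#' is public -- only cell values are bought), each cell's value where
#' opened and `NA` where still hidden, and the costs so far.
#'
#' @param state An `mlq_round`.
#' @return A list with `config`, `criterion`, `cells` (matrix with `NA`
#'   for hidden cells), `opened` (logical matrix), `ticks`, `cost`.
#' @export
round_view <- function(state) {
  stopifnot(inherits(state, "mlq_round"))
  cells <- state$board$cells
  cells[!state$opened] <- NA_integer_
  list(config = state$config,
       criterion = state$board$criterion,
       cells = cells,
       opened = state$opened,
       ticks = state$ticks,
       cost = round_cost_accrued(state))
}

# Visible criterion matches per row (hidden cells count 0).
visible_matches <- function(view) {
  na <- view$config$n_alternatives
  nk <- view$config$n_attributes
  crit <- matrix(view$criterion, na, nk, byrow = TRUE)
  rowSums(view$cells == crit, na.rm = TRUE)
}

# Decision noise: with prob error_rate swap the intended choice for a
# uniformly drawn other alternative. Consumes the current RNG stream.
noisy_choice <- function(intended, n_alternatives, error_rate) {
  if (error_rate > 0 && stats::runif(1) < error_rate) {
    others <- setdiff(seq_len(n_alternatives), intended)
    intended <- others[sample.int(length(others), 1)]
  }
  list(type = "choose", alternative = intended)
}

first_hidden_colmajor <- function(view) {
  idx <- which(!view$opened)  # column-major by construction
  pos <- arrayInd(idx[1], dim(view$opened))
  list(type = "open", alternative = pos[1], attribute = pos[2])
}

#' Next action under a policy
#'
#' Pure in the board view (each policy recomputes its plan from what is
#' visible) but draws from the current RNG stream for random choices and
#' decision noise. Returns a single legal action: an `"open"` action with
#' `alternative`/`attribute`, or a `"choose"` action with `alternative`.
#' Policies never emit `"tick"` actions; time is charged by the simulator
#' as actions execute (see [policy()]).
#'
#' @param pol An [policy()].
#' @param view A [round_view()].
#' @return An action list, as consumed by [play_round()].
#' @export
decide_next <- function(pol, view) {
  stopifnot(inherits(pol, "mlq_policy"))
  n_alt <- view$config$n_alternatives
  switch(pol$kind,
    random = list(type = "choose", alternative = sample.int(n_alt, 1)),
    exhaustive = decide_exhaustive(pol, view),
    take_the_best = decide_ttb(pol, view),
    satisficing = decide_satisficing(pol, view),
    weighted_additive = decide_wadd(pol, view)
  )
}

decide_exhaustive <- function(pol, view) {
  if (any(!view$opened)) return(first_hidden_colmajor(view))
  best <- which.max(visible_matches(view))
  noisy_choice(best, view$config$n_alternatives, pol$error_rate)
}

decide_wadd <- function(pol, view) {
  if (any(!view$opened)) return(first_hidden_colmajor(view))
  w <- pol$weights
  if (is.null(w)) w <- rev(seq_len(view$config$n_attributes))
  crit <- matrix(view$criterion, nrow(view$cells), ncol(view$cells), byrow = TRUE)
  score <- as.vector((view$cells == crit) %*% w)
  noisy_choice(which.max(score), view$config$n_alternatives, pol$error_rate)
}

decide_ttb <- function(pol, view) {
  n_alt <- view$config$n_alternatives
  priority <- pol$priority
  if (is.null(priority)) priority <- seq_len(view$config$n_attributes)
  candidates <- seq_len(n_alt)
  for (a in priority) {
    hidden <- candidates[is.na(view$cells[candidates, a])]
    if (length(hidden) > 0) {
      return(list(type = "open", alternative = hidden[1], attribute = a))
    }
    matching <- candidates[view$cells[candidates, a] == view$criterion[a]]
    if (length(matching) == 1) {
      return(noisy_choice(matching, n_alt, pol$error_rate))
    }
    if (length(matching) > 1) candidates <- matching
    # a cue matched by none of the candidates does not discriminate
  }
  noisy_choice(candidates[1], n_alt, pol$error_rate)
}

decide_satisficing <- function(pol, view) {
  n_alt <- view$config$n_alternatives
  nk <- view$config$n_attributes
  k <- min(pol$threshold, nk)
  for (alt in seq_len(n_alt)) {
    row <- view$cells[alt, ]
    matches <- sum(row == view$criterion, na.rm = TRUE)
    if (matches >= k) return(noisy_choice(alt, n_alt, pol$error_rate))
    hidden <- which(is.na(row))
    if (matches + length(hidden) < k) next  # threshold out of reach: move on
    return(list(type = "open", alternative = alt, attribute = hidden[1]))
  }
  # nothing satisfices: fall back to the best of what was seen
  noisy_choice(which.max(visible_matches(view)), n_alt, pol$error_rate)
}
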