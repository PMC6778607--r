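#' Start a round
#'
#' Creates the state machine for one round of the game: a hidden board, an
#' empty set of opened cells, zero elapsed time, and no choice yet. Costs
#' accrue as cells are opened ([reveal_cell()]) and time passes
#' ([advance_time()]); the round ends with [choose_alternative()] or, for a
#' no-response round, by being recorded unfinished.
#'
#' @param config A [game_config()].
#' @param board An `mlq_board` from [generate_board()].
#' @return An object of class `mlq_round`.
#' @export
new_round <- function(config, board) {
  validate_game_config(config)
  stopifnot(inherits(board, "mlq_board"))
  if (nrow(board$cells) != config$n_alternatives ||
      ncol(board$cells) != config$n_attributes) {
    stop("board dimensions do not match config")
  }
  state <- list(
    config = config,
    board = board,
    opened = matrix(FALSE, config$n_alternatives, config$n_attributes),
    opened_order = matrix(integer(0), ncol = 2,
                          dimnames = list(NULL, c("alternative", "attribute"))),
    ticks = 0L,
    chosen = NA_integer_,
    correct = NA,
    banked = 0L,
    forfeited = 0L,
    finished = FALSE
  )
  class(state) <- "mlq_round"
  state
}

#' Cost accrued so far in a round
#'
#' Always equals `opened cells x cell_cost + ticks x step_cost`; under the
#' default economy, 450 IRR per opened cell plus 780 IRR per time step.
#'
#' @param state An `mlq_round`.
#' @return Cost in IRR (integer).
#' @export
round_cost_accrued <- function(state) {
  stopifnot(inherits(state, "mlq_round"))
  sum(state$opened) * state$config$cell_cost + state$ticks * state$config$step_cost
}

check_cell_index <- function(state, alternative, attribute) {
  if (length(alternative) != 1 || is.na(alternative) ||
      alternative < 1 || alternative > state$config$n_alternatives) {
    stop("alternative index out of range [1, ", state$config$n_alternatives,
         "]: ", alternative)
  }
  if (length(attribute) != 1 || is.na(attribute) ||
      attribute < 1 || attribute > state$config$n_attributes) {
    stop("attribute index out of range [1, ", state$config$n_attributes,
         "]: ", attribute)
  }
}

#' Open (purchase) a cell
#'
#' Reveals the binary value at (`alternative`, `attribute`) for the cell
#' cost. Once purchased, a cell stays open for the rest of the round;
#' re-opening an already-open cell is an idempotent no-op with no further
#' charge.
#'
#' @param state An `mlq_round`, not yet finished.
#' @param alternative Row index (1-based).
#' @param attribute Column index (1-based).
#' @return The updated `mlq_round`.
#' @export
reveal_cell <- function(state, alternative, attribute) {
  stopifnot(inherits(state, "mlq_round"))
  if (state$finished) stop("round is finished; no further actions allowed")
  check_cell_index(state, alternative, attribute)
  alternative <- as.integer(alternative)
  attribute <- as.integer(attribute)
  if (!state$opened[alternative, attribute]) {
    state$opened[alternative, attribute] <- TRUE
    state$opened_order <- rbind(state$opened_order, c(alternative, attribute))
  }
  state
}

#' Let time pass
#'
#' Adds `ticks` discrete time steps, each charged at the step cost (the
#' "time pressure" channel of the economy).
#'
#' @param state An `mlq_round`, not yet finished.
#' @param ticks Non-negative integer number of steps.
#' @return The updated `mlq_round`.
#' @export
advance_time <- function(state, ticks = 1L) {
  stopifnot(inherits(state, "mlq_round"))
  if (state$finished) stop("round is finished; no further actions allowed")
  if (length(ticks) != 1 || is.na(ticks) || ticks < 0 || ticks != as.integer(ticks)) {
    stop("ticks must be a single non-negative integer")
  }
  state$ticks <- state$ticks + as.integer(ticks)
  state
}

#' Commit to an alternative and settle the round
#'
#' Ends the round. If the chosen row is the board's correct alternative,
#' the remaining allocation (`round_allocation - cost`, floored at 0) is
#' banked; otherwise it is forfeited -- a wrong choice loses the whole
#' reward of the round. The cost itself is always spent, so a round's net
#' can be negative when search spending exceeds the allocation.
#'
#' (Named `choose_alternative` because base R already uses `choose` for
#' binomial coefficients.)
#'
#' @param state An `mlq_round`, not yet finished.
#' @param alternative Row index to commit to.
#' @return The finished `mlq_round`, with `chosen`, `correct`, `banked`
#'   and `forfeited` filled in; see [round_outcome()].
#' @export
choose_alternative <- function(state, alternative) {
  stopifnot(inherits(state, "mlq_round"))
  if (state$finished) stop("round is finished; choice already made")
  if (length(alternative) != 1 || is.na(alternative) ||
      alternative < 1 || alternative > state$config$n_alternatives) {
    stop("alternative index out of range [1, ", state$config$n_alternatives,
         "]: ", alternative)
  }
  state$chosen <- as.integer(alternative)
  state$correct <- state$chosen == state$board$correct_alternative
  remainder <- max(0L, state$config$round_allocation - round_cost_accrued(state))
  if (state$correct) {
    state$banked <- remainder
    state$forfeited <- 0L
  } else {
    state$banked <- 0L
    state$forfeited <- remainder
  }
  state$finished <- TRUE
  state
}

#' Outcome of a settled (or abandoned) round
#'
#' @param state An `mlq_round`.
#' @return A list with `correct` (logical, `NA` if no choice was made),
#'   `cost`, `banked` and `forfeited`, all in IRR. For an unfinished round
#'   the full remaining allocation counts as forfeited, as for a wrong
#'   choice. Whenever `cost <= round_allocation`,
#'   `banked + forfeited + cost == round_allocation`.
#' @export
round_outcome <- function(state) {
  stopifnot(inherits(state, "mlq_round"))
  cost <- round_cost_accrued(state)
  if (state$finished) {
    list(correct = state$correct, cost = cost,
         banked = state$banked, forfeited = state$forfeited)
  } else {
    list(correct = NA, cost = cost, banked = 0L,
         forfeited = max(0L, state$config$round_allocation - cost))
  }
}

# ---- round records -------------------------------------------------------

new_round_record <- function(round_index, opened_cells, ticks, chosen,
                             correct, cost, banked, forfeited) {
  rec <- list(
    round_index = as.integer(round_index),
    opened_cells = opened_cells,
    ticks = as.integer(ticks),
    chosen = if (is.na(chosen)) NA_integer_ else as.integer(chosen),
    correct = correct,
    cost = as.integer(cost),
    banked = as.integer(banked),
    forfeited = as.integer(forfeited)
  )
  class(rec) <- "mlq_round_record"
  rec
}

round_record_from_state <- function(state, round_index) {
  out <- round_outcome(state)
  new_round_record(round_index,
                   opened_cells = state$opened_order,
                   ticks = state$ticks,
                   chosen = state$chosen,
                   correct = out$correct,
                   cost = out$cost,
                   banked = out$banked,
                   forfeited = out$forfeited)
}

#' Play one round from an explicit action list
#'
#' Drives [reveal_cell()], [advance_time()] and [choose_alternative()] from
#' a scripted sequence and returns the per-round trace record. Actions are
#' lists with a `type` of `"open"` (fields `alternative`, `attribute`),
#' `"tick"` (field `n`, default 1), or `"choose"` (field `alternative`);
#' at most one `"choose"`, and it must come last. A round whose actions end
#' without a choice is recorded as a no-response round: nothing banked, the
#' full remaining allocation forfeited.
#'
#' @param config A [game_config()].
#' @param board An `mlq_board`.
#' @param actions List of action lists (possibly empty).
#' @param round_index Round number recorded in the output.
#' @return An `mlq_round_record`.
#' @examples
#' cfg <- game_config()
#' b <- generate_board(cfg, seed = 7)
#' acts <- c(lapply(1:4, function(a) list(type = "open", alternative = a, attribute = 1)),
#'           list(list(type = "tick", n = 3),
#'                list(type = "choose", alternative = b$correct_alternative)))
#' play_round(cfg, b, acts)$cost  # 4 x 450 + 3 x 780 = 4140
#' @export
play_round <- function(config, board, actions, round_index = 1L) {
  state <- new_round(config, board)
  if (!is.list(actions)) stop("actions must be a list of action lists")
  for (i in seq_along(actions)) {
    act <- actions[[i]]
    if (!is.list(act) || is.null(act$type)) {
      stop("malformed action at position ", i, ": need a list with a 'type'")
    }
    if (state$finished) {
      stop("malformed action sequence: action after the round's choice ",
           "(position ", i, ")")
    }
    state <- switch(act$type,
      open = reveal_cell(state, act$alternative, act$attribute),
      tick = advance_time(state, if (is.null(act$n)) 1L else act$n),
      choose = choose_alternative(state, act$alternative),
      stop("unknown action type at position ", i, ": '", act$type, "'")
    )
  }
  round_record_from_state(state, round_index)
}

#' @export
print.mlq_round_record <- function(x, ...) {
  outcome <- if (is.na(x$chosen)) "no response"
             else if (isTRUE(x$correct)) "correct" else "wrong"
  cat(sprintf("<round %d> opened %d, ticks %d, cost %d IRR, %s (banked %d, forfeited %d)\n",
              x$round_index, nrow(x$opened_cells), x$ticks, x$cost,
              outcome, x$banked, x$forfeited))
  invisible(x)
}

#' Final credit implied by a session's ledger
#'
#' The credit ledger starts at `initial_credit`; every round deducts its
#' search cost, and wrong or no-response rounds additionally forfeit the
#' remaining allocation (`max(0, round_allocation - cost)`). Equivalently,
#' when no round's cost exceeds its allocation, the final credit is the sum
#' over correct rounds of `round_allocation - cost`.
#'
#' @param trace A [subject_trace()].
#' @return Final total credit in IRR (may be negative if search spending
#'   exceeded allocations).
#' @export
final_credit <- function(trace) {
  stopifnot(inherits(trace, "mlq_trace"))
  cfg <- trace$config
  credit <- cfg$initial_credit
  for (rec in trace$rounds) {
    credit <- credit - rec$cost
    if (!isTRUE(rec$correct)) {
      credit <- credit - max(0L, cfg$round_allocation - rec$cost)
    }
  }
  credit
}
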