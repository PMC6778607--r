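#' A subject's process-tracing record
#'
#' A `subject_trace` is one simulated or recorded session: the game
#' configuration plus an ordered list of per-round records (cells opened in
#' order, elapsed ticks, the choice and its correctness, cost, banked and
#' forfeited amounts). It is the unit the metrics layer consumes.
#'
#' @param subject_id Character id for the subject.
#' @param config The [game_config()] the session was played under.
#' @param rounds List of `mlq_round_record`s, round indices strictly
#'   increasing from 1.
#' @return An object of class `mlq_trace`.
#' @export
subject_trace <- function(subject_id, config, rounds) {
  trace <- list(subject_id = as.character(subject_id),
                config = config, rounds = rounds)
  class(trace) <- "mlq_trace"
  validate_trace(trace)
  trace
}

#' Validate a subject trace
#'
#' Enforces the record invariants: round indices strictly increasing from
#' 1; per-round cost exactly `unique opened cells x cell_cost +
#' ticks x step_cost`; a round with no choice has no correctness flag and
#' nothing banked; banked/forfeited consistent with the correctness flag.
#'
#' @param trace An `mlq_trace`.
#' @return `trace`, invisibly, or a descriptive error.
#' @export
validate_trace <- function(trace) {
  stopifnot(inherits(trace, "mlq_trace"))
  cfg <- validate_game_config(trace$config)
  idx <- vapply(trace$rounds, function(r) r$round_index, integer(1))
  if (length(idx) > 0 && !identical(idx, seq_len(length(idx)))) {
    stop("round indices must be strictly increasing from 1")
  }
  for (rec in trace$rounds) {
    n_open <- nrow(unique(rec$opened_cells))
    expected <- n_open * cfg$cell_cost + rec$ticks * cfg$step_cost
    if (rec$cost != expected) {
      stop("round ", rec$round_index, ": cost ", rec$cost,
           " does not equal opened*cell_cost + ticks*step_cost = ", expected)
    }
    if (is.na(rec$chosen)) {
      if (!is.na(rec$correct)) {
        stop("round ", rec$round_index, ": no choice made but correctness flag set")
      }
      if (rec$banked != 0L) {
        stop("round ", rec$round_index, ": no choice made but banked != 0")
      }
    } else {
      if (is.na(rec$correct)) {
        stop("round ", rec$round_index, ": choice made but correctness flag missing")
      }
      if (isTRUE(rec$correct) && rec$forfeited != 0L) {
        stop("round ", rec$round_index, ": correct choice but forfeited != 0")
      }
      if (!isTRUE(rec$correct) && rec$banked != 0L) {
        stop("round ", rec$round_index, ": wrong choice but banked != 0")
      }
    }
  }
  invisible(trace)
}

#' @export
print.mlq_trace <- function(x, ...) {
  cat(sprintf("<mlq_trace> subject %s: %d rounds (config: %d x %d board)\n",
              x$subject_id, length(x$rounds),
              x$config$n_alternatives, x$config$n_attributes))
  invisible(x)
}

#' One row per round, as a data frame
#'
#' @param x An `mlq_trace`.
#' @param ... Unused.
#' @return A data.frame with columns `subject_id`, `round`, `n_opened`,
#'   `ticks`, `chosen`, `correct`, `cost`, `banked`, `forfeited`.
#' @export
as.data.frame.mlq_trace <- function(x, ...) {
  data.frame(
    subject_id = x$subject_id,
    round = vapply(x$rounds, function(r) r$round_index, integer(1)),
    n_opened = vapply(x$rounds, function(r) nrow(r$opened_cells), integer(1)),
    ticks = vapply(x$rounds, function(r) r$ticks, integer(1)),
    chosen = vapply(x$rounds, function(r) r$chosen, integer(1)),
    correct = vapply(x$rounds, function(r) as.logical(r$correct), logical(1)),
    cost = vapply(x$rounds, function(r) r$cost, integer(1)),
    banked = vapply(x$rounds, function(r) r$banked, integer(1)),
    forfeited = vapply(x$rounds, function(r) r$forfeited, integer(1)),
    stringsAsFactors = FALSE
  )
}
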