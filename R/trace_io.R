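#' Trace file format
#'
#' Traces are stored as UTF-8 comma-separated text, one file per subject:
#'
#' * Pragma header lines: `#%mouselabq-trace v1`, then
#'   `#%config <JSON>` (the full [game_config()] as a flat JSON object),
#'   then `#%subject <id>`.
#' * A CSV header `subject_id,round,event_type,alternative,attribute,correct,running_cost`
#'   followed by one row per event. `event_type` is `open` (fields
#'   `alternative`, `attribute`), `tick` (one row per elapsed time step),
#'   or `choose` (fields `alternative`, `correct`). `running_cost` is the
#'   round's accrued cost, in IRR, *after* the event; the reader
#'   recomputes it from the economy and refuses files where they disagree.
#'
#' Within a round, events are written in normalized order (cell openings
#' in purchase order, then time steps, then the choice); the per-round
#' record keeps totals and purchase order, not the fine interleaving of
#' purchases and time. Rounds must appear in increasing order; a round
#' with no `choose` row -- or absent entirely -- is a no-response round.
#' Timestamps are integer tick counts, not wall-clock times: the economy
#' only ever consumes discrete steps.
#'
#' @name trace_format
NULL

trace_event_columns <- c("subject_id", "round", "event_type",
                         "alternative", "attribute", "correct", "running_cost")

#' Write a subject trace to a file
#'
#' Validates the trace (see [validate_trace()]) and writes it in the
#' documented plain-text schema (see [trace_format]). A trace violating
#' the cost invariant is refused.
#'
#' @param trace A [subject_trace()].
#' @param path Destination file path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  validate_trace(trace)
  cfg <- trace$config
  rows <- lapply(trace$rounds, function(rec) {
    n_ev <- nrow(rec$opened_cells) + rec$ticks + (!is.na(rec$chosen))
    if (n_ev == 0) return(NULL)
    ev <- data.frame(
      subject_id = trace$subject_id,
      round = rec$round_index,
      event_type = c(rep("open", nrow(rec$opened_cells)),
                     rep("tick", rec$ticks),
                     if (!is.na(rec$chosen)) "choose"),
      alternative = c(rec$opened_cells[, 1],
                      rep(NA_integer_, rec$ticks),
                      if (!is.na(rec$chosen)) rec$chosen),
      attribute = c(rec$opened_cells[, 2],
                    rep(NA_integer_, rec$ticks),
                    if (!is.na(rec$chosen)) NA_integer_),
      correct = c(rep(NA, nrow(rec$opened_cells) + rec$ticks),
                  if (!is.na(rec$chosen)) rec$correct),
      stringsAsFactors = FALSE
    )
    n_open_cum <- cumsum(ev$event_type == "open")
    n_tick_cum <- cumsum(ev$event_type == "tick")
    ev$running_cost <- n_open_cum * cfg$cell_cost + n_tick_cum * cfg$step_cost
    ev
  })
  events <- do.call(rbind, rows)
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(
    "#%mouselabq-trace v1",
    paste("#%config", jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE)),
    paste("#%subject", trace$subject_id)
  ), con)
  if (is.null(events)) {
    writeLines(paste(trace_event_columns, collapse = ","), con)
  } else {
    utils::write.csv(events[, trace_event_columns], con, row.names = FALSE,
                     quote = FALSE, na = "")
  }
  invisible(path)
}

parse_error <- function(line, msg) {
  stop(sprintf("trace parse error at line %d: %s", line, msg), call. = FALSE)
}

#' Read a subject trace from a file
#'
#' Parses the documented schema (see [trace_format]), recomputing every
#' event's running cost from the embedded economy and verifying it against
#' the file's `running_cost` column. Schema violations, cost mismatches
#' and out-of-order rounds raise descriptive errors naming the offending
#' line. Rounds of the configured session with no events are reconstructed
#' as zero-cost no-response rounds.
#'
#' @param path Path to a trace file.
#' @return A [subject_trace()].
#' @export
read_trace <- function(path) {
  if (!file.exists(path)) stop("trace file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) < 4 || !identical(lines[1], "#%mouselabq-trace v1")) {
    parse_error(1, "missing '#%mouselabq-trace v1' signature")
  }
  if (!startsWith(lines[2], "#%config ")) parse_error(2, "missing '#%config' pragma")
  cfg_raw <- jsonlite::fromJSON(sub("^#%config ", "", lines[2]))
  cfg <- do.call(game_config, cfg_raw)
  if (!startsWith(lines[3], "#%subject ")) parse_error(3, "missing '#%subject' pragma")
  subject_id <- sub("^#%subject ", "", lines[3])

  header_at <- 4L
  header <- strsplit(lines[header_at], ",", fixed = TRUE)[[1]]
  if (!identical(header, trace_event_columns)) {
    parse_error(header_at, paste0("expected header '",
                                  paste(trace_event_columns, collapse = ","), "'"))
  }
  body <- lines[-seq_len(header_at)]
  body_lineno <- header_at + seq_along(body)
  keep <- nzchar(trimws(body))
  body <- body[keep]; body_lineno <- body_lineno[keep]

  records <- vector("list", cfg$n_rounds)
  cur_round <- 0L
  opened <- NULL; n_ticks <- 0L; chosen <- NA_integer_; correct <- NA
  seen_choose <- FALSE

  flush_round <- function() {
    if (cur_round == 0L) return()
    cost <- nrow(opened) * cfg$cell_cost + n_ticks * cfg$step_cost
    remainder <- max(0L, cfg$round_allocation - cost)
    records[[cur_round]] <<- new_round_record(
      cur_round, opened, n_ticks, chosen,
      correct = if (is.na(chosen)) NA else correct,
      cost = cost,
      banked = if (isTRUE(correct)) remainder else 0L,
      forfeited = if (isTRUE(correct)) 0L else remainder)
  }

  for (i in seq_along(body)) {
    ln <- body_lineno[i]
    f <- strsplit(body[i], ",", fixed = TRUE)[[1]]
    length(f) <- length(trace_event_columns)
    names(f) <- trace_event_columns
    round <- suppressWarnings(as.integer(f["round"]))
    if (is.na(round) || round < 1) parse_error(ln, "bad or missing round number")
    if (round > cfg$n_rounds) {
      parse_error(ln, sprintf("round %d exceeds configured n_rounds %d",
                              round, cfg$n_rounds))
    }
    if (round < cur_round) {
      parse_error(ln, sprintf("out-of-order round: %d after %d", round, cur_round))
    }
    if (round > cur_round) {
      flush_round()
      cur_round <- round
      opened <- matrix(integer(0), ncol = 2,
                       dimnames = list(NULL, c("alternative", "attribute")))
      n_ticks <- 0L; chosen <- NA_integer_; correct <- NA; seen_choose <- FALSE
    }
    if (seen_choose) parse_error(ln, "event after the round's choice")
    type <- f[["event_type"]]
    alt <- suppressWarnings(as.integer(f["alternative"]))
    attr <- suppressWarnings(as.integer(f["attribute"]))
    if (identical(type, "open")) {
      if (is.na(alt)) parse_error(ln, "'open' event missing alternative")
      if (is.na(attr)) parse_error(ln, "'open' event missing attribute")
      if (alt < 1 || alt > cfg$n_alternatives || attr < 1 || attr > cfg$n_attributes) {
        parse_error(ln, "cell index out of board range")
      }
      if (!any(opened[, 1] == alt & opened[, 2] == attr)) {
        opened <- rbind(opened, c(alt, attr))
      }
    } else if (identical(type, "tick")) {
      n_ticks <- n_ticks + 1L
    } else if (identical(type, "choose")) {
      if (is.na(alt)) parse_error(ln, "'choose' event missing alternative")
      if (alt < 1 || alt > cfg$n_alternatives) {
        parse_error(ln, "chosen alternative out of range")
      }
      corr <- f[["correct"]]
      if (is.na(corr) || !corr %in% c("TRUE", "FALSE")) {
        parse_error(ln, "'choose' event needs correct=TRUE or FALSE")
      }
      chosen <- alt; correct <- identical(corr, "TRUE"); seen_choose <- TRUE
    } else {
      parse_error(ln, paste0("unknown event_type '", type, "'"))
    }
    expected_cost <- nrow(opened) * cfg$cell_cost + n_ticks * cfg$step_cost
    running <- suppressWarnings(as.integer(f["running_cost"]))
    if (is.na(running)) parse_error(ln, "missing running_cost")
    if (running != expected_cost) {
      parse_error(ln, sprintf(
        "running_cost %d disagrees with recomputed cost %d", running, expected_cost))
    }
  }
  flush_round()

  empty <- vapply(records, is.null, logical(1))
  for (r in which(empty)) {
    records[[r]] <- new_round_record(
      r, matrix(integer(0), ncol = 2,
                dimnames = list(NULL, c("alternative", "attribute"))),
      ticks = 0L, chosen = NA_integer_, correct = NA, cost = 0L,
      banked = 0L, forfeited = cfg$round_allocation)
  }
  subject_trace(subject_id, cfg, records)
}
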