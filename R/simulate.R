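#' Simulate one subject's session
#'
#' Plays `config$n_rounds` rounds under a single [policy()], each on a
#' freshly generated board, and returns the complete process trace. Time
#' is charged as actions execute: each cell purchase consumes
#' `ticks_per_action` time steps and the final commitment one further
#' step. The whole session is driven by one RNG stream seeded with `seed`,
#' so equal seeds give identical traces.
#'
#' @param config A [game_config()].
#' @param pol A [policy()].
#' @param seed Integer seed for the subject's stream.
#' @param subject_id Identifier stored in the trace.
#' @return A [subject_trace()].
#' @examples
#' tr <- simulate_subject(game_config(), policy("take_the_best"), seed = 1)
#' head(as.data.frame(tr))
#' @export
simulate_subject <- function(config, pol, seed, subject_id = "S1") {
  validate_game_config(config)
  stopifnot(inherits(pol, "mlq_policy"))
  rounds <- withr::with_seed(as.integer(seed), {
    lapply(seq_len(config$n_rounds), function(r) {
      board <- generate_board_impl(config)
      simulate_round(config, board, pol, r)
    })
  })
  subject_trace(subject_id, config, rounds)
}

simulate_round <- function(config, board, pol, round_index) {
  state <- new_round(config, board)
  if (pol$noresponse_rate > 0 && stats::runif(1) < pol$noresponse_rate) {
    # the agent freezes: deliberation time passes, but no choice is made
    state <- advance_time(state, 1L)
    state <- idle_to_target(state, pol, final_tick = FALSE)
    return(round_record_from_state(state, round_index))
  }
  max_actions <- config$n_alternatives * config$n_attributes + 2L
  for (i in seq_len(max_actions)) {
    act <- decide_next(pol, round_view(state))
    if (act$type == "open") {
      state <- advance_time(state, pol$ticks_per_action)
      state <- reveal_cell(state, act$alternative, act$attribute)
    } else if (act$type == "choose") {
      state <- idle_to_target(state, pol, final_tick = TRUE)
      state <- advance_time(state, 1L)
      state <- choose_alternative(state, act$alternative)
      break
    } else {
      stop("policy emitted unsupported action type: ", act$type)
    }
  }
  if (!state$finished) stop("policy failed to finish the round")
  round_record_from_state(state, round_index)
}

# Deliberation: idle until the round's cost is within one (or, before a
# final choice tick, two) step costs of the policy's spend target.
idle_to_target <- function(state, pol, final_tick) {
  if (is.na(pol$spend_target) || state$config$step_cost == 0) return(state)
  reserve <- if (final_tick) 1L else 0L
  room <- pol$spend_target - round_cost_accrued(state)
  extra <- floor(room / state$config$step_cost) - reserve
  if (extra > 0) state <- advance_time(state, extra)
  state
}

#' Simulate a cohort of subjects
#'
#' One trace per policy, each on an independent stream derived from the
#' master seed (sub-seeds are drawn once from the master stream, so the
#' whole cohort is reproducible from a single integer).
#'
#' @param config A [game_config()].
#' @param policies Non-empty list of [policy()] objects; names, if any,
#'   become subject ids (default `S01`, `S02`, ...).
#' @param seed Master integer seed.
#' @return A list of [subject_trace()]s.
#' @export
simulate_cohort <- function(config, policies, seed) {
  validate_game_config(config)
  if (!is.list(policies) || length(policies) == 0) {
    stop("policies must be a non-empty list of policy objects")
  }
  for (p in policies) stopifnot(inherits(p, "mlq_policy"))
  n <- length(policies)
  sub_seeds <- withr::with_seed(as.integer(seed),
                                sample.int(.Machine$integer.max - 1L, n))
  ids <- names(policies)
  if (is.null(ids)) ids <- sprintf("S%02d", seq_len(n))
  lapply(seq_len(n), function(i) {
    simulate_subject(config, policies[[i]], sub_seeds[i], ids[i])
  })
}

#' The default 17-agent roster
#'
#' A frozen mix of heuristic agents emulating a 17-subject cohort with the
#' marginal statistics a human information-board cohort shows under this
#' economy: partial information acquisition (roughly 40-45% of cells
#' bought), accuracy well above the 25% chance rate (roughly 75-80%
#' correct), per-round spending approaching the 15,000 IRR allocation, and
#' an occasional lapsed round. The mix (take-the-best, satisficing,
#' weighted-additive and exhaustive searchers with varying decision noise
#' and time use, plus one fast guesser) was fixed once by a documented
#' grid search over rosters; see the package vignette.
#'
#' @return A named list of 17 [policy()] objects.
#' @export
default_cohort_policies <- function() {
  pols <- list(
    policy("take_the_best", spend_target = 14400),
    policy("take_the_best", spend_target = 14100, priority = c(2L, 1L, 4L, 3L)),
    policy("take_the_best", spend_target = 13800, priority = c(4L, 3L, 2L, 1L)),
    policy("take_the_best", spend_target = 14550, priority = c(1L, 3L, 2L, 4L)),
    policy("take_the_best", error_rate = 0.03, spend_target = 14250,
           priority = c(3L, 4L, 1L, 2L)),
    policy("take_the_best", error_rate = 0.03, spend_target = 14400),
    policy("take_the_best", error_rate = 0.05, spend_target = 14400,
           noresponse_rate = 0.02),
    policy("satisficing", threshold = 3L, spend_target = 14400),
    policy("satisficing", threshold = 3L, spend_target = 14250,
           noresponse_rate = 0.02),
    policy("satisficing", threshold = 3L, error_rate = 0.03,
           spend_target = 14100),
    policy("satisficing", threshold = 3L, error_rate = 0.03,
           spend_target = 14400),
    policy("satisficing", threshold = 4L, spend_target = 13950),
    policy("satisficing", threshold = 4L, spend_target = 14400),
    policy("satisficing", threshold = 4L, spend_target = 14250),
    policy("satisficing", threshold = 2L, spend_target = 14100),
    policy("weighted_additive", error_rate = 0.05, ticks_per_action = 0L,
           spend_target = 14250),
    policy("random", spend_target = 13800)
  )
  names(pols) <- sprintf("S%02d", seq_along(pols))
  pols
}

#' Read a policy roster from a YAML or JSON file
#'
#' The file is a list of mappings, each with a `kind` plus any
#' kind-specific parameters accepted by [policy()]; list names (or a
#' `subject_id` key) become subject ids.
#'
#' @param path Path to the roster file.
#' @return A named list of [policy()] objects.
#' @export
read_policies <- function(path) {
  if (!file.exists(path)) stop("policies file not found: ", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  if (!is.list(raw) || length(raw) == 0) {
    stop("policies file must contain a non-empty list: ", path)
  }
  ids <- names(raw)
  if (is.null(ids)) ids <- rep("", length(raw))
  pols <- vector("list", length(raw))
  for (i in seq_along(raw)) {
    spec <- raw[[i]]
    if (!is.list(spec) || is.null(spec$kind)) {
      stop("policy entry ", i, " must be a mapping with a 'kind'")
    }
    if (!is.null(spec$subject_id)) {
      if (ids[i] == "") ids[i] <- spec$subject_id
      spec$subject_id <- NULL
    }
    if (!is.null(spec$priority)) spec$priority <- as.integer(spec$priority)
    if (!is.null(spec$weights)) spec$weights <- as.numeric(spec$weights)
    pols[[i]] <- do.call(policy, spec)
  }
  ids[ids == ""] <- sprintf("S%02d", which(ids == ""))
  names(pols) <- ids
  pols
}

#' Write a policy roster to a YAML file
#'
#' @param policies Named list of [policy()] objects.
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_policies <- function(policies, path) {
  out <- lapply(policies, function(p) {
    spec <- unclass(p)
    spec[!vapply(spec, is.null, logical(1))]
  })
  yaml::write_yaml(out, path)
  invisible(path)
}
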