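#' Game configuration: the economy of the information board
#'
#' A `game_config` bundles every economic constant of the task: the board
#' dimensions, the price of revealing one cell, the price of one elapsed
#' time step, the credit allocated to each round, the number of rounds, and
#' the session's initial credit. The defaults are the economy used
#' throughout this package's documentation: a 4 alternatives x 4 binary
#' attributes board, 450 IRR per opened cell, 780 IRR per time step, a
#' 15,000 IRR per-round allocation, and 60 rounds backed by 900,000 IRR of
#' initial credit (60 x 15,000).
#'
#' All monetary amounts are non-negative integers (whole IRR); fractional
#' money is never produced anywhere in the package.
#'
#' @param n_alternatives Number of alternatives (board rows).
#' @param n_attributes Number of binary attributes (board columns).
#' @param cell_cost Cost, in IRR, of opening one cell.
#' @param step_cost Cost, in IRR, of one elapsed time step.
#' @param round_allocation Credit, in IRR, allocated to each round.
#' @param n_rounds Number of rounds in a session.
#' @param initial_credit Total credit, in IRR, at the start of a session.
#'   Defaults to `n_rounds * round_allocation`.
#'
#' @return An object of class `game_config` (a named list).
#' @examples
#' cfg <- game_config()
#' cfg$round_allocation            # 15000
#' cfg$initial_credit / cfg$n_rounds  # 15000: the per-round allocation
#' @export
game_config <- function(n_alternatives = 4L,
                        n_attributes = 4L,
                        cell_cost = 450L,
                        step_cost = 780L,
                        round_allocation = 15000L,
                        n_rounds = 60L,
                        initial_credit = n_rounds * round_allocation) {
  cfg <- list(
    n_alternatives = as.integer(n_alternatives),
    n_attributes = as.integer(n_attributes),
    cell_cost = as.integer(cell_cost),
    step_cost = as.integer(step_cost),
    round_allocation = as.integer(round_allocation),
    n_rounds = as.integer(n_rounds),
    initial_credit = as.integer(initial_credit)
  )
  class(cfg) <- "game_config"
  validate_game_config(cfg)
}

#' Validate a game configuration
#'
#' Checks the structural invariants of a [game_config()]: positive counts,
#' non-negative integer monetary fields, and a board small enough that a
#' unique best-match alternative can always be found
#' (`n_alternatives < 2^n_attributes`, so that distinct rows exist).
#'
#' @param cfg A `game_config`.
#' @return `cfg`, invisibly unchanged, or an error.
#' @export
validate_game_config <- function(cfg) {
  stopifnot(inherits(cfg, "game_config"))
  fields <- c("n_alternatives", "n_attributes", "cell_cost", "step_cost",
              "round_allocation", "n_rounds", "initial_credit")
  missing <- setdiff(fields, names(cfg))
  if (length(missing) > 0) {
    stop("game_config is missing fields: ", paste(missing, collapse = ", "))
  }
  for (f in fields) {
    v <- cfg[[f]]
    if (length(v) != 1 || is.na(v) || v != as.integer(v)) {
      stop("game_config field '", f, "' must be a single integer")
    }
  }
  if (cfg$n_alternatives < 2) stop("n_alternatives must be >= 2")
  if (cfg$n_attributes < 1) stop("n_attributes must be >= 1")
  if (cfg$n_rounds < 1) stop("n_rounds must be >= 1")
  if (cfg$cell_cost < 0 || cfg$step_cost < 0 ||
      cfg$round_allocation < 0 || cfg$initial_credit < 0) {
    stop("monetary fields must be non-negative")
  }
  if (cfg$n_alternatives >= 2^cfg$n_attributes) {
    stop("n_alternatives must be < 2^n_attributes so a unique ",
         "best-match alternative always exists")
  }
  invisible(cfg)
}

#' @export
print.game_config <- function(x, ...) {
  cat("<game_config>\n")
  cat(sprintf("  board: %d alternatives x %d attributes\n",
              x$n_alternatives, x$n_attributes))
  cat(sprintf("  cell cost: %d IRR   step cost: %d IRR\n",
              x$cell_cost, x$step_cost))
  cat(sprintf("  rounds: %d   allocation/round: %d IRR   initial credit: %d IRR\n",
              x$n_rounds, x$round_allocation, x$initial_credit))
  invisible(x)
}

#' Read a game configuration from a YAML or JSON file
#'
#' The file is a flat mapping whose keys are exactly the [game_config()]
#' field names; missing keys take the default economy. The dialect is
#' chosen by extension (`.json` for JSON, anything else parsed as YAML,
#' of which JSON is a subset).
#'
#' @param path Path to the configuration file.
#' @return A `game_config`.
#' @export
read_game_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (!is.list(raw)) stop("config file must be a flat key/value mapping: ", path)
  known <- names(formals(game_config))
  bad <- setdiff(names(raw), known)
  if (length(bad) > 0) {
    stop("unknown config keys in ", path, ": ", paste(bad, collapse = ", "))
  }
  do.call(game_config, raw)
}

#' Write a game configuration to a YAML file
#'
#' @param cfg A `game_config`.
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_game_config <- function(cfg, path) {
  validate_game_config(cfg)
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}
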