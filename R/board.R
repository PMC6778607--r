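#' Generate one round's information board
#'
#' A board is an `n_alternatives x n_attributes` matrix of hidden binary
#' cells (1 = "Yes", 0 = "No") together with a binary criterion vector of
#' length `n_attributes`. The correct alternative of the round is the row
#' that matches the criterion on the largest number of attributes; cells
#' and criterion are resampled until that maximum is attained by exactly
#' one row, so every board has a well-defined correct answer.
#'
#' The rejection loop terminates with probability one because, with
#' `n_alternatives < 2^n_attributes`, the event that one row uniquely
#' attains the maximum match count has positive probability under uniform
#' sampling (for the default 4 x 4 board it is 37812/65536, about 0.577).
#'
#' @param config A [game_config()].
#' @param seed Integer seed; equal seeds give identical boards.
#' @return An object of class `mlq_board`: a list with `cells` (binary
#'   matrix), `criterion` (binary vector), `correct_alternative` (row
#'   index), and an `attempts` field counting how many candidate boards
#'   were sampled before one was accepted (1 = first draw accepted).
#' @examples
#' b <- generate_board(game_config(), seed = 7)
#' b$correct_alternative
#' @export
generate_board <- function(config, seed) {
  validate_game_config(config)
  withr::with_seed(as.integer(seed), generate_board_impl(config))
}

# Samples from the current RNG stream; used directly by the simulator so
# one subject-level stream drives all of a session's boards.
generate_board_impl <- function(config) {
  na <- config$n_alternatives
  nk <- config$n_attributes
  attempts <- 0L
  repeat {
    attempts <- attempts + 1L
    cells <- matrix(sample(c(0L, 1L), na * nk, replace = TRUE),
                    nrow = na, ncol = nk)
    criterion <- sample(c(0L, 1L), nk, replace = TRUE)
    matches <- rowSums(cells == matrix(criterion, na, nk, byrow = TRUE))
    top <- which(matches == max(matches))
    if (length(top) == 1L) {
      board <- list(cells = cells, criterion = criterion,
                    correct_alternative = top, attempts = attempts)
      class(board) <- "mlq_board"
      return(board)
    }
  }
}

#' Number of criterion matches per alternative
#'
#' @param board An `mlq_board`.
#' @return Integer vector: for each row, how many of its attributes equal
#'   the criterion.
#' @export
board_matches <- function(board) {
  stopifnot(inherits(board, "mlq_board"))
  na <- nrow(board$cells)
  nk <- ncol(board$cells)
  rowSums(board$cells == matrix(board$criterion, na, nk, byrow = TRUE))
}

#' @export
print.mlq_board <- function(x, ...) {
  cat("<mlq_board>", nrow(x$cells), "x", ncol(x$cells), "\n")
  m <- ifelse(x$cells == 1L, "Y", "N")
  rownames(m) <- paste0(ifelse(seq_len(nrow(m)) == x$correct_alternative,
                               "*alt", " alt"), seq_len(nrow(m)))
  colnames(m) <- paste0("attr", seq_len(ncol(m)))
  print(m, quote = FALSE)
  cat("criterion:", paste(ifelse(x$criterion == 1L, "Y", "N"), collapse = " "),
      "  (* = correct alternative)\n")
  invisible(x)
}
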