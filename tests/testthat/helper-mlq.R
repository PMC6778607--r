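# Shared fixtures and independent oracles.

# A board built by hand (bypassing the generator) for scripted scenarios.
make_board <- function(cells, criterion) {
  cells <- matrix(as.integer(cells), nrow = nrow(cells))
  matches <- rowSums(cells == matrix(as.integer(criterion), nrow(cells),
                                     ncol(cells), byrow = TRUE))
  top <- which(matches == max(matches))
  stopifnot(length(top) == 1)
  structure(list(cells = cells, criterion = as.integer(criterion),
                 correct_alternative = top, attempts = 1L),
            class = "mlq_board")
}

# 4x4 board whose unique best match is alternative 2 (criterion all-yes);
# attribute 1 already separates alternative 2 from the rest.
board_alt2_leads <- function() {
  make_board(rbind(c(0, 1, 1, 0),
                   c(1, 1, 1, 0),
                   c(0, 0, 1, 1),
                   c(0, 1, 0, 1)),
             criterion = c(1, 1, 1, 1))
}

# The two-round worked session: round 1 correct at cost 4140 (4 cells,
# 3 ticks), round 2 wrong at cost 6600 (6 cells, 5 ticks).
worked_config <- function() game_config(n_rounds = 2L)

worked_trace <- function() {
  cfg <- worked_config()
  b <- board_alt2_leads()
  acts1 <- c(lapply(1:4, function(a) list(type = "open", alternative = a, attribute = 1)),
             list(list(type = "tick", n = 3),
                  list(type = "choose", alternative = 2)))
  open2 <- list(c(1, 1), c(1, 2), c(2, 1), c(2, 2), c(3, 1), c(3, 2))
  acts2 <- c(lapply(open2, function(p) list(type = "open", alternative = p[1],
                                            attribute = p[2])),
             list(list(type = "tick", n = 5),
                  list(type = "choose", alternative = 3)))
  subject_trace("W1", cfg, list(play_round(cfg, b, acts1, 1L),
                                play_round(cfg, b, acts2, 2L)))
}

# Independent product-moment oracle: textbook formula plus the t transform.
oracle_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  r <- sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
  t_stat <- r * sqrt(n - 2) / sqrt(1 - r^2)
  p <- 2 * stats::pt(abs(t_stat), df = n - 2, lower.tail = FALSE)
  list(r = r, p = p)
}

# Type-7 quantile written out longhand, as a spreadsheet would do it.
oracle_quantile <- function(x, p) {
  s <- sort(x)
  h <- (length(s) - 1) * p + 1
  lo <- floor(h)
  s[lo] + (h - lo) * (s[min(lo + 1, length(s))] - s[lo])
}

# Exhaustive enumeration: fraction of raw boards (4 alternatives, 4 binary
# attributes, criterion fixed at all-yes) whose best-match row is unique.
# By symmetry the criterion does not matter, so this is the generator's
# acceptance probability.
oracle_unique_best_fraction <- function() {
  pc <- vapply(0:15, function(v) sum(bitwAnd(v, c(1L, 2L, 4L, 8L)) > 0),
               numeric(1))
  g <- expand.grid(r1 = 0:15, r2 = 0:15, r3 = 0:15, r4 = 0:15)
  m <- cbind(pc[g$r1 + 1], pc[g$r2 + 1], pc[g$r3 + 1], pc[g$r4 + 1])
  mx <- pmax(m[, 1], m[, 2], m[, 3], m[, 4])
  mean(rowSums(m == mx) == 1)
}

# Small session for round-trip and property tests.
small_config <- function() game_config(n_rounds = 12L)
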