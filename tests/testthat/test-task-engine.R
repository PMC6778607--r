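test_that("the default economy is internally consistent and validated", {
  cfg <- game_config()
  expect_identical(cfg$initial_credit, cfg$n_rounds * cfg$round_allocation)
  expect_identical(cfg$initial_credit %/% cfg$n_rounds, cfg$round_allocation)
  expect_error(game_config(cell_cost = -1), "non-negative")
  expect_error(game_config(n_alternatives = 1), ">= 2")
  # a unique best row must be guaranteed to exist
  expect_error(game_config(n_alternatives = 16, n_attributes = 4), "2\\^")
})

test_that("opening cells charges the cell cost once per cell", {
  st <- new_round(game_config(), board_alt2_leads())
  expect_identical(round_cost_accrued(st), 0L)
  st <- reveal_cell(st, 1, 1)
  expect_identical(round_cost_accrued(st), 450L)
  st2 <- reveal_cell(st, 1, 1)  # idempotent: cells stay open
  expect_identical(st2, st)
  expect_error(reveal_cell(st, 5, 1), "out of range")
  expect_error(reveal_cell(st, 1, 0), "out of range")
})

test_that("time steps charge the step cost", {
  st <- reveal_cell(new_round(game_config(), board_alt2_leads()), 1, 1)
  st <- advance_time(st, 1)
  expect_identical(round_cost_accrued(st), 1230L)  # 450 + 780
  expect_identical(advance_time(st, 0), st)
  st0 <- new_round(game_config(), board_alt2_leads())
  expect_identical(round_cost_accrued(advance_time(st0, 3)), 2340L)
  expect_error(advance_time(st0, -1), "non-negative")
})

test_that("choosing settles the round: bank on correct, forfeit on wrong", {
  cfg <- game_config()
  b <- board_alt2_leads()
  st <- new_round(cfg, b)
  for (a in 1:4) st <- reveal_cell(st, a, 1)
  st <- advance_time(st, 3)  # cost 4*450 + 3*780 = 4140
  correct <- choose_alternative(st, 2)
  expect_identical(round_outcome(correct)[c("banked", "forfeited")],
                   list(banked = 10860L, forfeited = 0L))
  expect_true(round_outcome(correct)$correct)
  expect_error(choose_alternative(correct, 1), "already made")
  expect_error(reveal_cell(correct, 1, 1), "finished")

  st6 <- new_round(cfg, b)
  for (p in list(c(1, 1), c(1, 2), c(2, 1), c(2, 2), c(3, 1), c(3, 2))) {
    st6 <- reveal_cell(st6, p[1], p[2])
  }
  st6 <- advance_time(st6, 5)  # cost 6*450 + 5*780 = 6600
  wrong <- choose_alternative(st6, 3)
  out <- round_outcome(wrong)
  expect_false(out$correct)
  expect_identical(out[c("cost", "banked", "forfeited")],
                   list(cost = 6600L, banked = 0L, forfeited = 8400L))
  # conservation: banked + forfeited + cost == allocation while cost <= allocation
  expect_identical(out$banked + out$forfeited + out$cost, cfg$round_allocation)
})

test_that("guessing with nothing opened is legal", {
  st <- choose_alternative(new_round(game_config(), board_alt2_leads()), 1)
  out <- round_outcome(st)
  expect_identical(out$cost, 0L)
  expect_false(out$correct)
})

test_that("play_round drives a scripted action list", {
  cfg <- game_config()
  b <- board_alt2_leads()
  rec <- play_round(cfg, b, c(
    lapply(1:4, function(a) list(type = "open", alternative = a, attribute = 1)),
    list(list(type = "tick", n = 3), list(type = "choose", alternative = 2))))
  expect_identical(rec$cost, 4140L)
  expect_true(rec$correct)
  expect_identical(rec$banked, 10860L)

  empty <- play_round(cfg, b, list())
  expect_identical(empty$cost, 0L)
  expect_true(is.na(empty$chosen))
  expect_identical(empty$forfeited, 15000L)

  all16 <- expand.grid(a = 1:4, k = 1:4)
  rec16 <- play_round(cfg, b, c(
    lapply(seq_len(16), function(i) list(type = "open",
                                         alternative = all16$a[i],
                                         attribute = all16$k[i])),
    list(list(type = "choose", alternative = 2))))
  expect_identical(nrow(rec16$opened_cells), 16L)
  expect_identical(rec16$cost, 16L * 450L)  # information cost only, no ticks

  expect_error(play_round(cfg, b, list(list(type = "choose", alternative = 1),
                                       list(type = "tick"))),
               "after the round's choice")
  expect_error(play_round(cfg, b, list(list(type = "warp"))), "unknown action")
})

test_that("board generation is deterministic, binary, and uniquely resolved", {
  cfg <- game_config()
  b1 <- generate_board(cfg, seed = 7)
  b2 <- generate_board(cfg, seed = 7)
  expect_identical(b1, b2)
  for (s in 1:25) {
    b <- generate_board(cfg, s)
    expect_true(all(b$cells %in% c(0L, 1L)))
    m <- board_matches(b)
    expect_identical(which(m == max(m)), b$correct_alternative)
  }
})

test_that("the correct alternative is uniform across seeds", {
  cfg <- game_config()
  winners <- vapply(1:400, function(s) generate_board(cfg, s)$correct_alternative,
                    integer(1))
  expect_gt(stats::chisq.test(tabulate(winners, 4))$p.value, 0.001)
})

test_that("the generator's acceptance rate matches exhaustive enumeration", {
  p_exact <- oracle_unique_best_fraction()
  expect_equal(p_exact, 37812 / 65536)
  cfg <- game_config()
  attempts <- vapply(1:2000, function(s) generate_board(cfg, s)$attempts,
                     integer(1))
  p_hat <- length(attempts) / sum(attempts)
  # ~4 sd of the inverse-geometric estimate at n = 2000
  expect_lt(abs(p_hat - p_exact), 0.035)
})

test_that("the session ledger conserves credit", {
  cfg <- small_config()
  for (pol in list(policy("take_the_best", spend_target = 14400),
                   policy("satisficing", threshold = 3),
                   policy("random"),
                   policy("exhaustive", ticks_per_action = 0L))) {
    tr <- simulate_subject(cfg, pol, seed = 11)
    df <- as.data.frame(tr)
    alloc <- cfg$round_allocation
    direct <- cfg$initial_credit - sum(df$cost) -
      sum(pmax(0, alloc - df$cost)[!df$correct %in% TRUE])
    via_correct <- sum((alloc - df$cost)[df$correct %in% TRUE]) +
      sum(pmin(0, alloc - df$cost)[!df$correct %in% TRUE])
    expect_equal(final_credit(tr), direct)
    expect_equal(direct, via_correct)
  }
})
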