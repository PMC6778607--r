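test_that("round costs combine information cost and time pressure", {
  cfg <- game_config()
  tr <- worked_trace()
  expect_equal(round_cost(tr$rounds[[1]], cfg), 4140)  # 4*450 + 3*780
  expect_equal(round_cost(tr$rounds[[2]], cfg), 6600)  # 6*450 + 5*780
  empty <- play_round(cfg, board_alt2_leads(), list())
  expect_equal(round_cost(empty, cfg), 0)
  all16 <- play_round(cfg, board_alt2_leads(), c(
    lapply(seq_len(16), function(i) list(type = "open",
                                         alternative = (i - 1) %% 4 + 1,
                                         attribute = (i - 1) %/% 4 + 1)),
    list(list(type = "choose", alternative = 2))))
  expect_equal(round_cost(all16, cfg), 7200)  # 16*450
})

test_that("the worked session reproduces the economics by hand", {
  tr <- worked_trace()
  expect_equal(expected_value(tr), 19260)        # (15000-4140) + (15000-6600)
  expect_equal(incorrect_choice_cost(tr), 8400)  # round 2 forfeits 15000-6600
  expect_equal(utility(tr), 10860)
  expect_equal(choice_quality(tr), 10860 / 19260 * 100, tolerance = 1e-12)
  expect_equal(round(choice_quality(tr), 2), 56.39)
})

test_that("utility is identically expected value minus incorrect-choice cost", {
  cfg <- small_config()
  for (s in 1:5) {
    tr <- simulate_subject(cfg, policy("take_the_best", error_rate = 0.2,
                                       spend_target = 14400), seed = s)
    expect_equal(utility(tr), expected_value(tr) - incorrect_choice_cost(tr))
    # with no cost above the allocation, utility is exactly the bank
    df <- as.data.frame(tr)
    if (all(df$cost <= cfg$round_allocation)) {
      expect_equal(utility(tr),
                   sum((cfg$round_allocation - df$cost)[df$correct %in% TRUE]))
      expect_equal(utility(tr), final_credit(tr))
    }
  }
})

test_that("choice quality is 100 for all-correct and 0 for all-wrong traces", {
  cfg <- worked_config()
  b <- board_alt2_leads()
  go <- function(alt, r) play_round(cfg, b, list(list(type = "tick", n = 2),
                                                 list(type = "choose", alternative = alt)),
                                    r)
  all_correct <- subject_trace("ac", cfg, list(go(2, 1), go(2, 2)))
  expect_equal(choice_quality(all_correct), 100)
  all_wrong <- subject_trace("aw", cfg, list(go(1, 1), go(4, 2)))
  expect_equal(choice_quality(all_wrong), 0)
})

test_that("choice quality refuses a non-positive expected value", {
  cfg <- worked_config()
  b <- board_alt2_leads()
  # 16 cells + 10 ticks = 15000 spent per round: expected value is zero
  burn <- function(alt, r) {
    all16 <- expand.grid(a = 1:4, k = 1:4)
    play_round(cfg, b, c(
      lapply(seq_len(16), function(i) list(type = "open", alternative = all16$a[i],
                                           attribute = all16$k[i])),
      list(list(type = "tick", n = 10), list(type = "choose", alternative = alt))),
      r)
  }
  tr <- subject_trace("burn", cfg, list(burn(2, 1), burn(2, 2)))
  expect_equal(expected_value(tr), 0)
  expect_error(choice_quality(tr), "undefined")
  expect_warning(m <- subject_metrics(tr), "choice quality")
  expect_true(is.na(m$choice_quality))
})

test_that("forfeits floor at zero when a round's cost exceeds its allocation", {
  cfg <- worked_config()
  b <- board_alt2_leads()
  all16 <- expand.grid(a = 1:4, k = 1:4)
  over <- play_round(cfg, b, c(   # 16*450 + 11*780 = 15780 > 15000
    lapply(seq_len(16), function(i) list(type = "open", alternative = all16$a[i],
                                         attribute = all16$k[i])),
    list(list(type = "tick", n = 11), list(type = "choose", alternative = 1))))
  expect_identical(over$forfeited, 0L)
  cheap <- play_round(cfg, b, list(list(type = "choose", alternative = 2)), 2L)
  tr <- subject_trace("over", cfg, list(over, cheap))
  expect_equal(incorrect_choice_cost(tr), 0)  # the overspent wrong round adds nothing
  expect_equal(choice_quality(tr), 100)       # no positive remainder was missed
})

test_that("flipping a correct round to wrong lowers choice quality only", {
  tr <- worked_trace()
  ev_before <- expected_value(tr)
  cq_before <- choice_quality(tr)
  flipped <- tr
  flipped$rounds[[1]]$correct <- FALSE
  flipped$rounds[[1]]$chosen <- 3L
  flipped$rounds[[1]]$forfeited <- flipped$rounds[[1]]$banked
  flipped$rounds[[1]]$banked <- 0L
  expect_equal(expected_value(flipped), ev_before)
  expect_lt(choice_quality(flipped), cq_before)
})

test_that("choice quality is invariant to rescaling the currency", {
  cfg1 <- worked_config()
  cfg3 <- game_config(cell_cost = 1350, step_cost = 2340,
                      round_allocation = 45000, n_rounds = 2L)
  rounds_at <- function(cfg) {
    b <- board_alt2_leads()
    list(play_round(cfg, b, c(
           lapply(1:4, function(a) list(type = "open", alternative = a, attribute = 1)),
           list(list(type = "tick", n = 3), list(type = "choose", alternative = 2)))),
         play_round(cfg, b, list(list(type = "tick", n = 5),
                                 list(type = "choose", alternative = 1)), 2L))
  }
  t1 <- subject_trace("x1", cfg1, rounds_at(cfg1))
  t3 <- subject_trace("x3", cfg3, rounds_at(cfg3))
  expect_equal(expected_value(t3), 3 * expected_value(t1))
  expect_equal(choice_quality(t3), choice_quality(t1), tolerance = 1e-12)
})

test_that("search and accuracy statistics count what happened", {
  cfg <- game_config()
  pol <- policy("satisficing", threshold = 3, noresponse_rate = 0.05,
                spend_target = 14100)
  tr <- simulate_subject(cfg, pol, seed = 17)
  ss <- search_stats(tr)
  df <- as.data.frame(tr)
  expect_identical(ss$opened_total, sum(df$n_opened))
  expect_equal(ss$opened_fraction, sum(df$n_opened) / 960)
  expect_equal(ss$opened_per_round_mean, sum(df$n_opened) / 60)
  acc <- accuracy_stats(tr)
  expect_identical(acc$n_correct + acc$n_wrong + acc$n_noresponse, 60L)
  expect_equal(acc$correct_pct, acc$n_correct / 60 * 100)
})

test_that("cohort-mean worked examples print at the expected precision", {
  cfg <- game_config()
  expect_equal(round(search_fraction_pct(407.35, cfg), 2), 42.43)
  expect_equal(accuracy_pct(46.11, cfg), 76.85)
  expect_equal(search_fraction_pct(960, cfg), 100)
  expect_equal(search_fraction_pct(0, cfg), 0)
})

test_that("metrics from records agree with a replay through the engine", {
  cfg <- small_config()
  tr <- simulate_subject(cfg, policy("take_the_best", error_rate = 0.1,
                                     spend_target = 14250), seed = 23)
  recomputed <- vapply(tr$rounds, function(rec) round_cost(rec, cfg), numeric(1))
  expect_equal(recomputed, vapply(tr$rounds, function(r) as.numeric(r$cost),
                                  numeric(1)))
  expect_equal(expected_value(tr), sum(cfg$round_allocation - recomputed))
})
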