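# mouselabq

Information-board (Mouselab-style) choice games with a real cost of
information, and the **choice-quality** analysis built on them.

## The problem

Process-tracing experiments hide a matrix of binary attributes (columns)
for a set of alternatives (rows) behind cells that must be actively
revealed. When revealing a cell and letting time pass both cost credit,
and only a correct choice banks a round's remaining allocation, search
behaviour acquires a measurable economics: how much of the attainable gain
did a decision maker's choices actually realize, *given* the search costs
they chose to incur? That is the question the choice-quality index
answers, and this package implements both the task and the analysis for
researchers in behavioral decision science who want to simulate, score,
and tabulate such sessions reproducibly.

For a session with allocation $A$ per round and search cost $c_r$ in
round $r$:

- expected value: $\mathrm{EV} = \sum_r (A - c_r)$ — the gain ceiling the
  subject's spending left attainable;
- incorrect-choice cost:
  $\mathrm{ICC} = \sum_{r \notin \text{correct}} \max(0, A - c_r)$;
- utility (net profit): $U = \mathrm{EV} - \mathrm{ICC}$;
- **choice quality**: $\mathrm{CQ} = U/\mathrm{EV} \times 100$, in
  percent; 100 iff no round with a positive remainder was missed,
  undefined (an error, never a silent number) when $\mathrm{EV} \le 0$.

The default economy: a 4 × 4 board, 450 IRR per opened cell, 780 IRR per
time step, 15,000 IRR allocated per round, 60 rounds, 900,000 IRR initial
credit. Wrong (or unanswered) rounds forfeit their remainder; costs are
always spent.

The package has five layers: a game engine with an explicit credit
ledger; seeded synthetic agents (random, exhaustive, take-the-best,
satisficing, weighted-additive) that play sessions and emit
process-tracing logs; a validated plain-text trace format; per-subject
metrics; and cohort tables (descriptives plus a Pearson correlation
matrix with two-tailed significance).

## A worked example

One round, scripted by hand: open the four cells of attribute 1, let
three time steps pass, then choose the correct alternative.

```r
library(mouselabq)
cfg <- game_config()
b <- generate_board(cfg, seed = 7)
rec <- play_round(cfg, b, c(
  lapply(1:4, function(a) list(type = "open", alternative = a, attribute = 1)),
  list(list(type = "tick", n = 3),
       list(type = "choose", alternative = b$correct_alternative))))
rec
#> <round 1> opened 4, ticks 3, cost 4140 IRR, correct (banked 10860, forfeited 0)
```

The cost is 4 × 450 + 3 × 780 = 4140 IRR, and the correct choice banks
the remaining 15,000 − 4140 = 10,860 IRR. A whole session under a
take-the-best agent, scored:

```r
tr <- simulate_subject(cfg, policy("take_the_best", spend_target = 14400), seed = 1)
round(unlist(subject_metrics(tr)[c("opened_fraction", "correct_pct",
                                   "expected_value", "utility", "choice_quality")]), 2)
#> opened_fraction     correct_pct  expected_value         utility  choice_quality
#>            0.44           88.33        35850.00        30300.00           84.52
```

This agent bought 44% of the available cells, answered 88.33% of rounds
correctly, left itself a 35,850 IRR gain ceiling after search costs,
banked 30,300 IRR of it — realizing a choice quality of 84.52%.

Cohort-level, end to end (also available from the shell via
`inst/cli/mouselabq simulate|score|tables`):

```r
run_simulate(game_config(), default_cohort_policies(), seed = 11, out_dir = "run")
run_score("run", out_path = "run/metrics.csv")
run_tables("run/metrics.csv", "run/tables")   # Tables 1-3 as CSV + aligned text
```

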