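---
title: "Measuring choice quality in a cost-bearing information-board game"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring choice quality in a cost-bearing information-board game}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mouselabq)
```

## The task and its economy

An information board presents a matrix of alternatives (rows) by binary
attributes (columns) whose cell values are hidden. The decision maker may
*purchase* any cell to reveal it, and both purchases and elapsed time cost
credit. Each round has one objectively correct alternative -- the row that
matches a binary preference criterion on the largest number of attributes
-- and a fixed credit allocation. A correct choice banks whatever is left
of the allocation after search costs; a wrong choice (or a lapsed round)
forfeits it. Process tracing -- *which* cells were bought, in what order,
and how much time passed -- is recorded alongside the outcome.

`mouselabq` implements this task as a deterministic state machine with an
explicit credit ledger, plus everything needed to analyse play: synthetic
agents, a plain-text trace format, per-subject economics, and cohort
summary tables.

The default economy (all amounts in Iranian rial, IRR):

| parameter          | default | meaning                                   |
|--------------------|--------:|-------------------------------------------|
| `n_alternatives`   |       4 | board rows (options)                      |
| `n_attributes`     |       4 | board columns (binary cues)               |
| `cell_cost`        |     450 | price of revealing one cell               |
| `step_cost`        |     780 | price of one elapsed time step            |
| `round_allocation` |  15,000 | credit at stake each round                |
| `n_rounds`         |      60 | rounds per session                        |
| `initial_credit`   | 900,000 | session credit, `60 x 15,000`             |

Money is integer IRR throughout; a "time step" is an abstract discrete
unit (the economy never consumes fractional steps), so traces store tick
counts, not milliseconds.

## The analysis: expected value, utility, choice quality

For a session with per-round search costs $c_r$ and allocation $A$:

* **expected value** $\mathrm{EV} = \sum_r (A - c_r)$ -- the gain ceiling
  the subject's search spending left attainable, i.e. what they would have
  banked had every choice been correct. (Parts of the literature call this
  *expected utility*; the package standardizes on expected value.)
* **incorrect-choice cost**
  $\mathrm{ICC} = \sum_{r \notin \mathrm{correct}} \max(0, A - c_r)$ --
  the reward forgone on wrong and no-response rounds.
* **utility** $U = \mathrm{EV} - \mathrm{ICC}$ -- the net profit actually
  realized; with no round costing more than its allocation this equals the
  ledger's final credit.
* **choice quality** $\mathrm{CQ} = U / \mathrm{EV} \times 100$ -- the
  percentage of attainable net gains realized. It is 100 exactly when no
  round with a positive remainder was missed, 0 when none was captured,
  and undefined when $\mathrm{EV} \le 0$ (the package raises an error
  rather than report a number). Because numerator and denominator are both
  sums of money, CQ is invariant to rescaling the whole currency.

```{r worked}
cfg <- game_config()
b <- generate_board(cfg, seed = 7)
rec <- play_round(cfg, b, c(
  lapply(1:4, function(a) list(type = "open", alternative = a, attribute = 1)),
  list(list(type = "tick", n = 3),
       list(type = "choose", alternative = b$correct_alternative))))
rec  # cost 4*450 + 3*780 = 4140; banked 15000 - 4140 = 10860
```

### Numerical conventions

* Forfeits and banked amounts floor at zero when a round's cost exceeds
  its allocation, but the ledger still deducts the full cost, so a round's
  *net* can be negative. Nothing caps search spending.
* A round ended without a choice ("no response") forfeits like a wrong
  round but is counted separately in accuracy statistics.
* Percentages are printed to two decimals; all internal computation is
  full precision.

## Board generation

Cells and the criterion vector are sampled uniformly and the board is
resampled until exactly one row attains the maximum match count, so every
round has a well-defined correct answer. For the 4 x 4 board the
acceptance probability is 37812/65536 (about 0.577, verified in the test
suite by exhaustive enumeration), so the rejection loop terminates almost
surely and quickly. With the criterion fixed, the winning row is uniform
across alternatives by symmetry.

## Synthetic agents

No subject-level data accompany the analysis this package implements, so
cohorts are emulated by seeded agents spanning the classic strategy
families: `random` (buys nothing, guesses -- the 25% chance baseline),
`exhaustive` and `weighted_additive` (compensatory full search),
`take_the_best` (lexicographic cue use with early stopping) and
`satisficing` (aspiration threshold on matches). Two noise channels make
accuracy and spending continuously tunable:

* `error_rate` -- at the moment of choice the agent commits to a
  uniformly drawn other alternative with this probability. Decision noise,
  not perception noise: it is the simplest single parameter that moves
  accuracy between ceiling and chance.
* `spend_target` -- after deciding, the agent keeps deliberating (time
  steps elapse and are charged) until the round's cost approaches the
  target. This reproduces a time-pressure-dominated economy in which
  per-round spending approaches the allocation regardless of search depth.

Time accounting is linear: each cell purchase consumes `ticks_per_action`
steps (default 1), the final commitment one further step, and
`spend_target` deliberation whatever remains. The engine itself accepts
arbitrary explicit tick events, so externally recorded logs are not bound
to this convention.

### The default roster

`default_cohort_policies()` is a frozen roster of 17 agents (7
take-the-best with varying cue orders, 8 satisficers at thresholds 2-4,
one weighted-additive full searcher, one fast guesser; small decision
noise on some; two lapse occasionally). It was fixed once by a grid search
over rosters targeting the study conditions the analysis assumes -- about
40-45% of cells purchased, accuracy well above the 25% chance rate,
per-round spending approaching the 15,000 IRR allocation, positive
expected value for every subject -- and is not adjusted thereafter; tests
assert those ranges, not the calibration process.

```{r cohort}
m <- cohort_metrics(simulate_cohort(game_config(),
                                    default_cohort_policies(), seed = 11))
round(c(opened_fraction = mean(m$opened_fraction),
        correct_pct = mean(m$correct_pct),
        mean_cost_per_round = 15000 - mean(m$expected_value) / 60,
        choice_quality = mean(m$choice_quality)), 2)
```

### What the generator does and does not emulate

The roster reproduces the *marginal* statistics above, which is what the
downstream tables consume. It does not claim to match any real cohort's
strategy mix (no published per-subject classification exists to match),
does not model learning across rounds, fatigue, or mouse kinematics, and
one systematic difference is worth knowing: heuristic agents' intrinsic
errors concentrate in rounds where a single cue resolved early -- cheap
rounds with large remainders -- so the synthetic cohort's mean choice
quality (typically ~70%) runs a few points below its accuracy, more than
human cohorts show. Passing cohort-level tests therefore demonstrates
that the pipeline computes the right quantities under realistic marginal
conditions, not that the agents are a behavioural model of people.

## Trace format and validation

Traces are one CSV per subject with pragma headers carrying the full
configuration, one row per event (`open` / `tick` / `choose`) and a
`running_cost` column. The reader recomputes every running cost from the
economy and refuses files that disagree, as well as out-of-order rounds
and malformed events -- so a scored trace is guaranteed to satisfy the
same ledger the engine enforces. The schema is deliberately minimal; logs
from other information-board software can be adapted to it by mapping
their acquisition events onto `open`/`tick`/`choose` rows.

## Cohort statistics

`build_tables()` produces descriptives (mean, sample SD, median, IQR with
linearly interpolated type-7 quantiles -- the usual statistical-package
convention, stated here because the quantile convention is otherwise
ambiguous) and a full symmetric Pearson correlation matrix over the six
analysis variables, with two-tailed p values from
$t = r\sqrt{n-2}/\sqrt{1-r^2}$ on $n-2$ degrees of freedom and stars at
p < 0.05 / p < 0.01. p values below 0.001 are rendered `< 0.001`.
Correlations involving a constant variable are reported as undefined
rather than raising an error, so degenerate cohorts still tabulate.
`pearson_p_from_r()` exposes the t transform directly, which is how one
checks a published r/p pair for internal consistency when the raw data
are unavailable (at n = 17, r = 0.596 gives p = 0.012).

## Problem sizes and reproducibility

Everything is driven by explicit integer seeds: a cohort draws one
sub-seed per subject from the master stream, and a subject's whole
session runs on its own stream, so equal seeds give byte-identical traces
and the simulate-score-tables pipeline is deterministic end to end. The
bundled analyses use 60-round sessions for cohort work, 12-round sessions
for round-trip and invariant checks, and a 10,000-round session for the
random-choice baseline, which estimates the 25% chance rate to within
about 0.85 percentage points (95% binomial CI).

## Known limitations

* The correctness rule (unique best match to a binary criterion) is the
  simplest rule guaranteeing a well-defined answer; real deployments of
  such tasks sometimes use graded or weighted ground truths.
* One "time step" has no wall-clock definition here; only a display-level
  mapping would give seconds, and none is needed for the economics.
* The agents choose among at most `2^n_attributes` distinguishable rows;
  configurations with `n_alternatives >= 2^n_attributes` are rejected at
  validation because a unique best row could not be guaranteed.
* `run_score()` floors at the subject level: a subject whose expected
  value is non-positive gets `NA` choice quality (with a warning) so one
  pathological session cannot poison a cohort table.
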