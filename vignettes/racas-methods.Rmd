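---
title: "The RaCaS schedule: model, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The RaCaS schedule: model, assumptions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(racas)
```

## The task and the model

The setting is a 100-trial two-alternative forced-choice task under the
choice-engineering constraint: an allocation algorithm must place exactly 25
fixed-size rewards on each of the two options, deciding before every trial
which side(s) carry a reward, and may condition on the full history of the
decision-maker's choices. One option is designated the target (**Bias+**);
the algorithm's objective is to attract choices to it.

RaCaS ("Regularity as Carrot and Stick") pursues that objective not with
reward amounts — it cannot; totals are fixed — but with reward *structure*.
Its premises: (1) discovering and confirming a regular pattern is itself
reinforcing; (2) disrupting an acquired pattern is punishing; (3) a
decision-maker who has hypothesized a pattern will keep choosing the target
to confirm the hypothesis. The schedule therefore pays the Bias+ option at
predictable intervals that widen and then narrow over six stages (interval
parameter X = 1, 2, 3, 4, 3, 2 over trials 1–11, 12–25, 26–40, 41–60,
61–80, 81–100: after X non-rewarded Bias+ clicks, the next Bias+ click
pays), halts the pattern the moment the agent defects to Bias−, and resumes
it only after recommitment. Bias− rewards are concealed: granted only
simultaneously with a Bias+ reward while the agent is highly committed, with
any residue dumped into the final trials where a committed agent no longer
samples that side.

## The state machine

The scheduler is a pure, deterministic state machine; all stochasticity in a
simulation lives in the agent. Its memory is: the next trial index; the
cycle counter of committed Bias+ clicks since the last Bias+ reward; the
streak of consecutive non-rewarded clicks (either side); the run of
consecutive Bias+ choices; the two remaining budgets; and two flags,
`reset_mode` and `awaiting_recommit`. Allocation for a trial is decided
before the choice; a reward on a side the agent then fails to pick is
*spent*, not returned — the bookkeeping a fixed-budget competition requires,
and what makes "missed" rewards possible at all.

Per-trial event order in `run_session()` is fixed: allocate → choose →
reveal the outcome on the chosen side only → update the agent → advance the
scheduler.

Four rules interact:

* **Pattern rule.** A Bias+ reward is placed when the cycle counter has
  reached the effective X, the pattern is not suspended, and budget remains.
* **Suspension and recommitment.** A Bias− choice zeroes the cycle counter
  and run length and suspends the pattern. It resumes — cycle restarted —
  once the agent strings together `recommit_threshold` consecutive Bias+
  choices. The threshold defaults to 2, the smallest run distinguishable
  from a one-off return; it is a free parameter of the constructor because
  nothing in the schedule's logic pins it.
* **Reset.** Ten consecutive non-rewarded clicks set `reset_mode`, which
  forces effective X = 1 (one dry committed click, then pay) until the next
  obtained reward clears it. This re-engages an agent that has fallen out of
  the pattern entirely.
* **Forcing.** Per side, whenever the remaining trials no longer exceed the
  remaining budget, every remaining trial carries that side's reward. This
  is what guarantees exact conservation for *every* policy: the budget can
  never exceed the remaining trials, so both sides end at zero.

Bias− co-allocation fires when a Bias+ reward is being placed and the agent
has made at least `commitment_threshold` (default 5) consecutive Bias+
choices — the reward is then invisible unless the agent defects on exactly
that trial. The threshold is likewise configurable; 5 was chosen as a run
length clearly beyond the recommitment criterion, long enough to indicate
commitment rather than sampling.

Two further conventions: the cycle counter carries across stage boundaries
(the X in force at the moment of the click applies, so a boundary-crossing
inter-reward gap can differ from both stages' nominal gaps); and trial
indexing is 1-based with inclusive stage ranges.

For a fully committed agent these rules yield rewards at trials
`r paste(always_plus_reward_trials(), collapse = ", ")` — gaps of X+1
within each stage — with the Bias+ budget exhausted at trial 87, 23 Bias−
rewards co-allocated unseen, and the last 2 forced into trials 99–100.

## Agents

The agent library replaces human participants as the test harness; none is
fitted to human data.

* `always_plus` / `always_minus` — the degenerate policies that bound the
  schedule's behavior and make hand-verifiable oracles possible.
* `bernoulli(p_plus)` — memoryless; at p = 0.5 it defines chance-level
  earnings.
* `wsls(stay_reward, shift_noreward)` — probabilistic win-stay/lose-shift.
* `qlearn(alpha, epsilon, q0_plus, q0_minus)` — delta-rule value learning
  on the chosen side with ε-greedy choice; with α = 1, ε = 0 it degenerates
  to strict WSLS wherever the greedy comparison is determined (on value
  ties it randomizes, which WSLS does not).
* `regularity_seeker(commitment_gain, exploration_floor, commit_init)` — a
  documented demonstration heuristic for pattern-sensitivity: it tracks the
  click gap between successive Bias+ rewards, predicts the next gap as the
  last gap or one more (the schedule's widening steps), raises its
  commitment probability multiplicatively on confirmation, and lowers it
  when a reward is overdue or found on Bias−. It demonstrates that an agent
  valuing predictability commits harder than any reward-rate learner; it is
  not a cognitive model.

Each agent owns a private random stream (a stored `.Random.seed`
Mersenne-Twister state), swapped in around its draws, so sessions are
reproducible from `(spec, seed)` and never perturb the caller's RNG.
Batch seeds come from the splittable derivation
`(base + 7919·i + 104729·j) mod (2³¹ − 1)` over spec index i and replicate
j, so extending a batch preserves earlier sessions.

## Metrics and statistics

Per session: the Bias+ choice fraction over all 100 trials (no
missed-trial exclusions exist in simulation); Δrewards(norm.)
`(R₊ − R₋)/(R₊ + R₋)` over obtained rewards, in \[−1, 1\]; observed
expectancy (rewards won on an option / choices of it); exploitation
(rewards won on an option / the 25 allocated to it). These satisfy the
identity `obtained₊ = expectancy₊ · choices₊ = exploitation₊ · 25`, which
the test suite asserts on every simulated session. Ratios of the form 0/0
(a side never chosen; no reward obtained) are reported as `NA`, never
silently 0 — human datasets rarely hit these cases but degenerate
simulated policies do.

Group level: one- and two-sample Student *t* tests (pooled variance, two
tailed) via `stats::t.test`; Cohen's *d* with the sample SD (one-sample)
or pooled SD (two-sample); Spearman rank correlation via `stats::cor.test`
with the asymptotic p value so tied ranks are handled. Rolling averages
use a trailing window (default 10) with the warm-up trimmed; trailing
alignment was chosen because it is causal — the value at trial t uses only
trials ≤ t.

## What the simulations do and do not show

The synthetic agents emulate the task's mechanics exactly — 100 trials, 25
rewards per side, feedback only on the chosen option — and span policies
from fully committed to fully defecting. Passing tests therefore establish
the *scheduler's* properties: conservation under every policy, determinism
given the choice history, the stage structure, reset and recommitment
semantics, and chance-level expected earnings (exactly 25) for a fair-coin
agent, since allocation precedes and cannot anticipate the choice. They do
not establish anything about human behavior: no simulated agent here is a
validated model of human pattern-seeking, so the magnitude of bias a
schedule induces in people cannot be reproduced, only measured on real
session data imported through the mapping-driven export adapter
(`read_cec_export()`).

## Numerical and scale choices

Problem sizes in the tests were chosen to estimate each quantity to the
precision its assertion needs: conservation is checked over 10,000 sessions
spread across all agent kinds (it is exact, so one counterexample fails);
the fair-coin earnings mean uses 10,000 sessions and a 3-standard-error
band (SE ≈ 0.015 rewards); frequency checks on agents use binomial
3-standard-error bands. `scripts/acceptance.R` uses the same 10,000-session
design. All sweeps run in minutes on one CPU.

Degenerate inputs are errors, not guesses: zero-variance samples for
effect sizes and t machinery, windows longer than the series, incomplete
sessions for exploitation, out-of-range trial indices, overdrawn budgets.
Validation of session files is row-addressed (session id and trial) and the
CLI's `check` subcommand exits nonzero on the first violation.

## Known limitations

* The recommitment (2) and commitment (5) thresholds and the reset
  semantics are this package's own resolutions of genuinely open design
  points; both thresholds are constructor arguments so variants can be
  explored.
* The regularity_seeker is a demonstration device; conclusions about human
  regularity-seeking require fitting real data, which is out of scope.
* Response-time analyses and Bayesian model comparison are not implemented.
* The export adapter normalizes schemas by explicit column mapping; it does
  not guess an unknown file's coding.
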