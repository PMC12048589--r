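# racas

Simulation and analysis of **RaCaS** ("Regularity as Carrot and Stick"), a
dynamic reward-allocation algorithm for choice engineering: biasing a
decision-maker toward a target option in a 100-trial two-alternative task in
which exactly 25 fixed-size rewards must be allocated to each option. The
package is for computational cognitive scientists and behavioral modelers
who want to study how reward *regularity* — rather than reward *amount* —
steers choice, and to test reward-learning models against a schedule that
exploits pattern-seeking.

## The algorithm

Call the target option **Bias+** and the other **Bias−**. RaCaS allocates
rewards to Bias+ in a predictable pattern governed by an interval parameter
*X*: after *X* non-rewarded clicks on Bias+, the next Bias+ click pays. *X*
steps through six stages over the session,

| stage | trials | X |
|---|---|---|
| 0 | 1–11 | 1 |
| 1 | 12–25 | 2 |
| 2 | 26–40 | 3 |
| 3 | 41–60 | 4 |
| 4 | 61–80 | 3 |
| 5 | 81–100 | 2 |

so a committed agent is rewarded every 2nd click, then every 3rd, 4th, 5th,
4th, 3rd. The "carrot" is the trackable regularity; the "stick" is that a
single Bias− choice suspends the pattern until the agent recommits (two
consecutive Bias+ choices by default). Ten consecutive non-rewarded clicks
trigger a simplified schedule (effective *X* = 1) until the next obtained
reward, to re-engage a discouraged agent. The 25 Bias− rewards are hidden:
co-allocated with a Bias+ reward only while the agent is highly committed
(five consecutive Bias+ choices by default), with any residue forced into
the final trials. Per side, a forcing rule guarantees conservation: when the
remaining trials equal the remaining budget, every remaining trial carries
that side's reward. Allocation on a trial is decided *before* the choice and
a missed reward is spent, not returned.

Sessions are scored with the standard choice-engineering metrics: the Bias+
choice fraction; Δrewards(norm.) = (R₊ − R₋)/(R₊ + R₋) over obtained
rewards; observed expectancy (rewards won on an option / times it was
chosen); exploitation (rewards won on an option / 25 allocated to it);
rolling averages (window 10); Cohen's *d*; Student *t* tests; Spearman rank
correlation.

## Worked example

```r
library(racas)

# A fully committed agent collects all 25 Bias+ rewards at the scheduled
# intervals:
always_plus_reward_trials()
#>  [1]  2  4  6  8 10 13 16 19 22 25 29 33 37 42 47 52 57 61 65 69 73 77 81 84 87

# Pit a Q-learning agent against the scheduler:
s <- run_session(agent_spec("qlearn", list(alpha = 0.3, epsilon = 0.1)),
                 seed = 42)
print(as.data.frame(session_metrics(s)), digits = 4)
#>   session_id                                                  agent seed
#> 1       <NA> qlearn(alpha=0.3,epsilon=0.1,q0_plus=0.5,q0_minus=0.5)   42
#>   bias_plus delta_rewards_norm expectancy_plus expectancy_minus
#> 1      0.62                  1          0.4032                0
#>   exploitation_plus exploitation_minus total_obtained
#> 1                 1                  0             25
```

Here the schedule biased the learner to choose Bias+ on 62 of 100 trials;
Δrewards(norm.) = 1 means every reward it found was on the Bias+ side (it
discovered all 25 of them — exploitation 1 — and none of the hidden Bias−
rewards); expectancy 0.4032 is its empirical payoff rate per Bias+ click.

Batches, file I/O and group statistics:

```r
batch <- run_experiment(list(agent_spec("bernoulli"), agent_spec("qlearn")),
                        n_per_spec = 50, base_seed = 1)
write_sessions(batch, "sessions.csv")
group_stats(summarize_sessions(batch))   # per-agent bias, t vs 0.5, Cohen's d
```

The same operations are available from a shell via the bundled CLI
(`inst/cli/racas`): `simulate`, `analyze`, `fixtures`, and `check` (an
invariant audit that exits nonzero on any violation).

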