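# Independent brute-force oracle for the fully committed (always Bias+)
# agent. Deliberately written from scratch against the printed schedule,
# not via the package's state machine: the interval parameter is a literal
# if-chain over trial ranges, and the only mechanics are "after X
# non-rewarded clicks the next click pays" plus the 25-reward budget.
# (A fully committed agent never defects and never reaches ten consecutive
# non-rewarded clicks while budget remains, so recommitment and the reset
# rule cannot fire and are intentionally absent here.)
oracle_x_for_trial <- function(t) {
  if (t <= 11) 1L
  else if (t <= 25) 2L
  else if (t <= 40) 3L
  else if (t <= 60) 4L
  else if (t <= 80) 3L
  else 2L
}

oracle_always_plus_rewards <- function() {
  budget <- 25L
  counter <- 0L
  rewards <- integer(0)
  for (t in 1:100) {
    if (counter >= oracle_x_for_trial(t) && budget > 0L) {
      rewards <- c(rewards, t)
      budget <- budget - 1L
      counter <- 0L
    } else {
      counter <- counter + 1L
    }
  }
  rewards
}

# Shared small helpers for tests.
make_session <- function(kind, seed = 1L, params = list()) {
  run_session(agent_spec(kind, params, seed = seed), seed = seed)
}

# A spread of agent specs covering every kind, for sweep-style properties.
sweep_specs <- function() {
  list(
    agent_spec("always_plus"),
    agent_spec("always_minus"),
    agent_spec("bernoulli", list(p_plus = 0.5)),
    agent_spec("bernoulli", list(p_plus = 0.9)),
    agent_spec("wsls", list(stay_reward = 0.9, shift_noreward = 0.8)),
    agent_spec("qlearn", list(alpha = 0.3, epsilon = 0.1)),
    agent_spec("regularity_seeker")
  )
}
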