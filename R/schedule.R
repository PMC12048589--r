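# RaCaS scheduler: a pure, deterministic state machine that decides, before
# each trial, whether a reward is placed on the Bias+ and/or Bias- side,
# under the hard constraint of exactly 25 rewards per side over 100 trials.

#' Side labels
#'
#' Choices and allocations are coded with single-character side labels:
#' `"P"` for the Bias+ (target) option and `"M"` for the Bias- option.
#'
#' @format Character scalars.
#' @name sides
NULL

#' @rdname sides
#' @export
SIDE_PLUS <- "P"

#' @rdname sides
#' @export
SIDE_MINUS <- "M"

N_TRIALS <- 100L
REWARDS_PER_SIDE <- 25L

#' The six-stage interval table of the RaCaS schedule
#'
#' RaCaS steps the interval parameter `X` (the number of non-rewarded Bias+
#' clicks required before the next Bias+ click is rewarded) through six
#' stages over the 100 trials: X = 1, 2, 3, 4, 3, 2. Every (X+1)-th committed
#' Bias+ click is rewarded, so rewards arrive at predictable, incrementally
#' widening then narrowing intervals.
#'
#' @return A data frame with columns `stage` (0..5), `from`, `to` (inclusive
#'   1-based trial ranges partitioning 1..100) and `X`.
#' @examples
#' stage_table()
#' @export
stage_table <- function() {
  data.frame(
    stage = 0:5,
    from  = c(1L, 12L, 26L, 41L, 61L, 81L),
    to    = c(11L, 25L, 40L, 60L, 80L, 100L),
    X     = c(1L, 2L, 3L, 4L, 3L, 2L)
  )
}

# X in force at each trial, as a flat lookup (hot path of allocate_trial).
X_BY_TRIAL <- rep(c(1L, 2L, 3L, 4L, 3L, 2L),
                  times = c(11L, 14L, 15L, 20L, 20L, 20L))

#' Stage and interval parameter for a trial
#'
#' @param t Trial index or vector of indices, 1-based, in 1..100.
#' @return A data frame with one row per element of `t` and columns
#'   `stage` (0..5) and `X` (interval parameter in force at that trial).
#' @examples
#' stage_for_trial(1)    # stage 0, X = 1
#' stage_for_trial(41)$X # 4
#' @export
stage_for_trial <- function(t) {
  if (length(t) == 0L || anyNA(t) || any(t != as.integer(t)) ||
      any(t < 1L) || any(t > N_TRIALS)) {
    stop("`t` must contain integer trial indices in 1..100", call. = FALSE)
  }
  tab <- stage_table()
  i <- findInterval(as.integer(t), tab$from)
  data.frame(stage = tab$stage[i], X = tab$X[i])
}

#' Create a fresh RaCaS schedule state
#'
#' The state is the scheduler's full memory: the next trial index, the
#' Bias+ reward-cycle click counter, the streak of consecutive non-rewarded
#' clicks, the run of consecutive Bias+ choices, the remaining per-side
#' reward budgets, and the two mode flags (`reset_mode`, set after ten
#' consecutive non-rewarded clicks and cleared by the next obtained reward;
#' `awaiting_recommit`, set by a Bias- choice and cleared by recommitment).
#'
#' @param recommit_threshold Consecutive Bias+ choices after a defection
#'   required before the reward pattern restarts (default 2, the smallest
#'   detectable recommitment).
#' @param commitment_threshold Consecutive Bias+ choices required before a
#'   Bias- reward may be co-allocated alongside a Bias+ reward (default 5).
#' @return An object of class `racas_schedule`.
#' @examples
#' s <- schedule_new()
#' s$plus_budget # 25
#' @export
schedule_new <- function(recommit_threshold = 2L, commitment_threshold = 5L) {
  recommit_threshold <- as.integer(recommit_threshold)
  commitment_threshold <- as.integer(commitment_threshold)
  if (length(recommit_threshold) != 1L || is.na(recommit_threshold) ||
      recommit_threshold < 1L) {
    stop("`recommit_threshold` must be a single integer >= 1", call. = FALSE)
  }
  if (length(commitment_threshold) != 1L || is.na(commitment_threshold) ||
      commitment_threshold < 1L) {
    stop("`commitment_threshold` must be a single integer >= 1", call. = FALSE)
  }
  structure(
    list(
      trial = 1L,
      plus_cycle = 0L,
      unrewarded_streak = 0L,
      consecutive_plus = 0L,
      plus_budget = REWARDS_PER_SIDE,
      minus_budget = REWARDS_PER_SIDE,
      reset_mode = FALSE,
      awaiting_recommit = FALSE,
      recommit_threshold = recommit_threshold,
      commitment_threshold = commitment_threshold
    ),
    class = "racas_schedule"
  )
}

#' @export
print.racas_schedule <- function(x, ...) {
  cat("<racas_schedule> trial", x$trial,
      "| cycle", x$plus_cycle,
      "| streak", x$unrewarded_streak,
      "| consec+", x$consecutive_plus,
      "| budgets", x$plus_budget, "/", x$minus_budget,
      "| reset", x$reset_mode,
      "| awaiting_recommit", x$awaiting_recommit, "\n")
  invisible(x)
}

#' Decide the reward allocation for the upcoming trial
#'
#' Computed before (and independently of) the agent's upcoming choice; a pure
#' function of the schedule state, hence of the full choice/reward history.
#'
#' A Bias+ reward is placed when the cycle counter has reached the effective
#' interval parameter (the stage's X, or 1 while `reset_mode` simplifies the
#' schedule), the pattern is not suspended awaiting recommitment, and budget
#' remains; or when the remaining trials equal the remaining Bias+ budget, so
#' that every budgeted reward still fits (the forcing rule). A Bias- reward is
#' only ever hidden: co-allocated with a Bias+ reward once the agent has shown
#' sustained commitment to Bias+, or forced into the final trials.
#'
#' @param state A `racas_schedule` state with `trial <= 100`.
#' @return A list with logical fields `alloc_plus` and `alloc_minus`. Both
#'   may be `TRUE` on the same trial.
#' @examples
#' allocate_trial(schedule_new()) # no reward before a non-rewarded click
#' @export
allocate_trial <- function(state) {
  stopifnot(inherits(state, "racas_schedule"))
  t <- state$trial
  if (t > N_TRIALS) {
    stop("session complete: all 100 trials have been played", call. = FALSE)
  }
  remaining <- N_TRIALS + 1L - t
  x_eff <- if (state$reset_mode) 1L else X_BY_TRIAL[t]
  alloc_plus <-
    (state$plus_cycle >= x_eff && !state$awaiting_recommit &&
       state$plus_budget > 0L) ||
    remaining <= state$plus_budget
  alloc_minus <-
    (alloc_plus && state$consecutive_plus >= state$commitment_threshold &&
       state$minus_budget > 0L) ||
    remaining <= state$minus_budget
  list(alloc_plus = alloc_plus, alloc_minus = alloc_minus)
}

#' Advance the schedule state past one trial
#'
#' Applies the bookkeeping for one completed trial: budgets are decremented
#' for every allocated side whether or not the reward was obtained (a missed
#' reward is spent, not returned); the non-reward streak is reset by an
#' obtained reward and otherwise incremented, with the tenth consecutive
#' non-rewarded click triggering `reset_mode` (a simplified schedule with
#' effective X = 1 until the next obtained reward); a Bias+ choice extends
#' the commitment run and, when the pattern is live, advances the reward
#' cycle; a Bias- choice halts the pattern until recommitment (a run of
#' `recommit_threshold` consecutive Bias+ choices) is detected.
#'
#' @param state A `racas_schedule` state.
#' @param alloc The allocation produced by [allocate_trial()] on this state.
#' @param choice `"P"` (Bias+) or `"M"` (Bias-).
#' @return The successor `racas_schedule` state.
#' @export
advance_state <- function(state, alloc, choice) {
  stopifnot(inherits(state, "racas_schedule"))
  if (state$trial > N_TRIALS) {
    stop("session complete: all 100 trials have been played", call. = FALSE)
  }
  if (!(is.character(choice) && length(choice) == 1L &&
        choice %in% c(SIDE_PLUS, SIDE_MINUS))) {
    stop("`choice` must be \"P\" (Bias+) or \"M\" (Bias-)", call. = FALSE)
  }
  obtained <- (choice == SIDE_PLUS && alloc$alloc_plus) ||
    (choice == SIDE_MINUS && alloc$alloc_minus)

  if (alloc$alloc_plus) {
    if (state$plus_budget <= 0L) stop("Bias+ budget overdrawn", call. = FALSE)
    state$plus_budget <- state$plus_budget - 1L
  }
  if (alloc$alloc_minus) {
    if (state$minus_budget <= 0L) stop("Bias- budget overdrawn", call. = FALSE)
    state$minus_budget <- state$minus_budget - 1L
  }

  if (obtained) {
    state$unrewarded_streak <- 0L
    state$reset_mode <- FALSE
  } else {
    state$unrewarded_streak <- state$unrewarded_streak + 1L
    if (state$unrewarded_streak >= 10L) {
      state$reset_mode <- TRUE
      state$unrewarded_streak <- 0L
    }
  }

  if (choice == SIDE_PLUS) {
    state$consecutive_plus <- state$consecutive_plus + 1L
    if (state$awaiting_recommit) {
      if (state$consecutive_plus >= state$recommit_threshold) {
        state$awaiting_recommit <- FALSE
        state$plus_cycle <- 0L
      }
    } else {
      state$plus_cycle <- if (obtained) 0L else state$plus_cycle + 1L
    }
  } else {
    state$consecutive_plus <- 0L
    state$plus_cycle <- 0L
    state$awaiting_recommit <- TRUE
  }

  state$trial <- state$trial + 1L
  state
}

#' Reward trials of a fully committed agent
#'
#' Runs the scheduler against an agent that chooses Bias+ on every trial and
#' returns the trial indices at which that agent obtains a reward. Useful as
#' a readable summary of the schedule's regular structure: rewards fall at
#' stage-wise intervals of X+1 clicks (trials 2, 4, ..., 10 during stage 0)
#' until the 25-reward Bias+ budget is exhausted.
#'
#' @param schedule A fresh schedule state, by default [schedule_new()].
#' @return Integer vector of trial indices (length 25 for the defaults).
#' @examples
#' head(always_plus_reward_trials()) # 2 4 6 8 10 13
#' @export
always_plus_reward_trials <- function(schedule = schedule_new()) {
  state <- schedule
  out <- integer(0)
  for (t in seq_len(N_TRIALS)) {
    alloc <- allocate_trial(state)
    if (alloc$alloc_plus) out <- c(out, t)
    state <- advance_state(state, alloc, SIDE_PLUS)
  }
  out
}
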