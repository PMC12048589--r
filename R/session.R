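# Orchestrates one agent against the RaCaS scheduler for 100 trials.
# Per-trial event order: allocate -> choose -> reveal obtained -> update
# agent -> advance scheduler. The agent is only ever told the outcome on the
# side it chose.

#' Run one 100-trial session
#'
#' Pits one simulated agent against the RaCaS scheduler. The result is a
#' deterministic function of `(spec, seed, schedule thresholds)`.
#'
#' @param spec A [agent_spec()] describing the agent.
#' @param seed Seed of the agent's private random stream (defaults to the
#'   seed in `spec`).
#' @param schedule A fresh scheduler state, by default [schedule_new()];
#'   pass one built with different recommitment / commitment thresholds to
#'   vary the schedule variant.
#' @param session_id Optional identifier stored with the result.
#' @return An object of class `racas_session`: a list with `records` (a
#'   tibble of 100 rows with columns `trial`, `choice`, `alloc_plus`,
#'   `alloc_minus`, `obtained`), `agent` (label), `agent_spec`, `seed`,
#'   and `session_id`. Invariants (25 allocations per side; `obtained`
#'   consistent with choice and allocation) are asserted before returning.
#' @examples
#' s <- run_session(agent_spec("always_plus"), seed = 1)
#' sum(s$records$obtained) # 25
#' @export
run_session <- function(spec, seed = spec$seed, schedule = schedule_new(),
                        session_id = NULL) {
  stopifnot(inherits(spec, "racas_agent_spec"))
  state <- schedule
  agent <- agent_init(spec, seed)

  choice <- character(N_TRIALS)
  alloc_plus <- logical(N_TRIALS)
  alloc_minus <- logical(N_TRIALS)
  obtained <- logical(N_TRIALS)

  # Install the agent's private stream for the whole session (it is the
  # only random consumer here), restoring the caller's stream afterwards.
  old_rng <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  assign(".Random.seed", agent$rng, envir = globalenv())
  on.exit(rng_restore(old_rng), add = TRUE)

  for (t in seq_len(N_TRIALS)) {
    alloc <- allocate_trial(state)
    ch <- choose_impl(agent)
    agent <- ch$state
    side <- ch$choice
    got <- (side == SIDE_PLUS && alloc$alloc_plus) ||
      (side == SIDE_MINUS && alloc$alloc_minus)
    agent <- agent_update(agent, side, got)
    state <- advance_state(state, alloc, side)

    choice[t] <- side
    alloc_plus[t] <- alloc$alloc_plus
    alloc_minus[t] <- alloc$alloc_minus
    obtained[t] <- got
  }

  session <- structure(
    list(
      records = tibble::tibble(
        trial = seq_len(N_TRIALS),
        choice = choice,
        alloc_plus = alloc_plus,
        alloc_minus = alloc_minus,
        obtained = obtained
      ),
      agent = agent_label(spec),
      agent_spec = spec,
      seed = as.integer(seed),
      session_id = session_id
    ),
    class = "racas_session"
  )
  validate_session(session)
  session
}

#' Validate a session against the task invariants
#'
#' Asserts that a session has exactly 100 trials numbered 1..100, exactly
#' 25 rewards allocated to each side, and an `obtained` flag equal to
#' "the allocation on the chosen side" on every trial.
#'
#' @param session A `racas_session`.
#' @param id Label used in error messages (defaults to the session's id).
#' @return `session`, invisibly, if valid; otherwise an error naming the
#'   offending session and trial.
#' @export
validate_session <- function(session, id = NULL) {
  stopifnot(inherits(session, "racas_session"))
  r <- session$records
  id <- id %||% session$session_id %||% session$agent
  fail <- function(...) {
    stop("session '", id, "': ", ..., call. = FALSE)
  }
  if (nrow(r) != N_TRIALS || !identical(as.integer(r$trial), 1:100)) {
    fail("expected trials 1..100 exactly once, got ", nrow(r), " rows")
  }
  if (!all(r$choice %in% c(SIDE_PLUS, SIDE_MINUS))) {
    bad <- r$trial[!(r$choice %in% c(SIDE_PLUS, SIDE_MINUS))][1]
    fail("invalid choice code at trial ", bad)
  }
  if (sum(r$alloc_plus) != REWARDS_PER_SIDE) {
    fail("Bias+ allocations sum to ", sum(r$alloc_plus), ", expected 25")
  }
  if (sum(r$alloc_minus) != REWARDS_PER_SIDE) {
    fail("Bias- allocations sum to ", sum(r$alloc_minus), ", expected 25")
  }
  expect_obt <- ifelse(r$choice == SIDE_PLUS, r$alloc_plus, r$alloc_minus)
  if (!identical(as.logical(r$obtained), as.logical(expect_obt))) {
    bad <- r$trial[as.logical(r$obtained) != as.logical(expect_obt)][1]
    fail("`obtained` inconsistent with (choice, allocation) at trial ", bad)
  }
  invisible(session)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.racas_session <- function(x, ...) {
  cat("<racas_session>", x$session_id %||% "", x$agent, "seed", x$seed, "\n")
  cat("  obtained:", sum(x$records$obtained), "of 50 allocated;",
      "Bias+ choices:", sum(x$records$choice == SIDE_PLUS), "/ 100\n")
  invisible(x)
}

#' Derive a per-session seed for a batch
#'
#' Splittable derivation `(base + 7919*i + 104729*j) mod (2^31 - 1)` (both
#' multipliers prime), so every (spec index, replicate index) pair gets a
#' distinct, reproducible stream and batches can be extended without
#' reshuffling earlier sessions.
#'
#' @param base_seed Non-negative integer base seed.
#' @param spec_index 1-based index of the agent spec in the batch.
#' @param replicate 1-based replicate index.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(base_seed, spec_index, replicate) {
  as.integer((as.numeric(base_seed) + 7919 * as.numeric(spec_index) +
                104729 * as.numeric(replicate)) %% (2^31 - 1))
}

#' Run a batch of sessions
#'
#' @param specs A single [agent_spec()] or a list of them.
#' @param n_per_spec Number of replicate sessions per spec (>= 1).
#' @param base_seed Base seed; per-session seeds come from [derive_seed()].
#' @param schedule Scheduler passed to every session (default
#'   [schedule_new()]).
#' @return A list of `racas_session` objects, ordered by spec then
#'   replicate, with session ids `"s0001"`, `"s0002"`, ... and each
#'   labeled with its agent.
#' @examples
#' batch <- run_experiment(agent_spec("bernoulli"), n_per_spec = 2,
#'                         base_seed = 42)
#' vapply(batch, function(s) s$seed, integer(1))
#' @export
run_experiment <- function(specs, n_per_spec, base_seed = 0L,
                           schedule = schedule_new()) {
  if (inherits(specs, "racas_agent_spec")) specs <- list(specs)
  if (!is.list(specs) || length(specs) == 0L ||
      !all(vapply(specs, inherits, logical(1), "racas_agent_spec"))) {
    stop("`specs` must be a non-empty list of agent specs", call. = FALSE)
  }
  if (!(length(n_per_spec) == 1L && n_per_spec >= 1 &&
        n_per_spec == as.integer(n_per_spec))) {
    stop("`n_per_spec` must be an integer >= 1", call. = FALSE)
  }
  out <- vector("list", length(specs) * n_per_spec)
  k <- 0L
  for (i in seq_along(specs)) {
    for (j in seq_len(n_per_spec)) {
      k <- k + 1L
      out[[k]] <- run_session(
        specs[[i]],
        seed = derive_seed(base_seed, i, j),
        schedule = schedule,
        session_id = sprintf("s%04d", k)
      )
    }
  }
  out
}
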