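# Simulated decision-makers. Each agent chooses a side every trial and is
# updated on the outcome of its own choice only (feedback on the unchosen
# side is never revealed, matching the task). Every agent carries a private
# random stream derived from its seed, so full choice sequences are
# reproducible from (spec, seed) alone.

AGENT_KINDS <- c("always_plus", "always_minus", "bernoulli", "wsls",
                 "qlearn", "regularity_seeker")

#' Specify a simulated agent
#'
#' @param kind One of `"always_plus"`, `"always_minus"`, `"bernoulli"`,
#'   `"wsls"`, `"qlearn"`, `"regularity_seeker"`.
#' @param params Named list of kind-specific parameters:
#'   * `bernoulli`: `p_plus` in \[0,1\] (probability of choosing Bias+;
#'     default 0.5).
#'   * `wsls`: `stay_reward` (probability of repeating the last choice after
#'     a reward) and `shift_noreward` (probability of switching after a
#'     non-reward), both in \[0,1\]; defaults 1 and 1 give strict
#'     win-stay/lose-shift.
#'   * `qlearn`: learning rate `alpha` in (0,1\], exploration rate `epsilon`
#'     in \[0,1\], initial values `q0_plus`, `q0_minus` (defaults 0.1, 0.1,
#'     0.5, 0.5). Values are updated by the delta rule
#'     `V <- V + alpha * (r - V)` on the chosen side only.
#'   * `regularity_seeker`: `commitment_gain` in (0,1\] (step size of the
#'     commitment probability), `exploration_floor` in \[0,0.5) (the
#'     commitment probability is clamped to
#'     \[floor, 1-floor\]), `commit_init` in \[0,1\] (starting commitment;
#'     defaults 0.25, 0.05, 0.5). A heuristic that tracks the click
#'     interval between rewards obtained on Bias+ and commits harder when
#'     the unfolding interval pattern confirms its prediction.
#' @param seed Non-negative integer seeding the agent's private random
#'   stream.
#' @return An object of class `racas_agent_spec`.
#' @examples
#' agent_spec("bernoulli", list(p_plus = 0.5), seed = 1)
#' @seealso [agent_init()], [run_session()]
#' @export
agent_spec <- function(kind, params = list(), seed = 0L) {
  if (!(is.character(kind) && length(kind) == 1L && kind %in% AGENT_KINDS)) {
    stop("`kind` must be one of: ", paste(AGENT_KINDS, collapse = ", "),
         call. = FALSE)
  }
  if (!(length(seed) == 1L && !is.na(seed) && seed == as.integer(seed) &&
        seed >= 0)) {
    stop("invalid agent parameter `seed`: must be a non-negative integer",
         call. = FALSE)
  }
  params <- validate_agent_params(kind, params)
  structure(
    list(kind = kind, params = params, seed = as.integer(seed)),
    class = "racas_agent_spec"
  )
}

validate_agent_params <- function(kind, params) {
  if (!is.list(params)) stop("`params` must be a named list", call. = FALSE)
  defaults <- switch(kind,
    always_plus  = list(),
    always_minus = list(),
    bernoulli    = list(p_plus = 0.5),
    wsls         = list(stay_reward = 1, shift_noreward = 1),
    qlearn       = list(alpha = 0.1, epsilon = 0.1,
                        q0_plus = 0.5, q0_minus = 0.5),
    regularity_seeker = list(commitment_gain = 0.25,
                             exploration_floor = 0.05,
                             commit_init = 0.5)
  )
  unknown <- setdiff(names(params), names(defaults))
  if (length(unknown) > 0L) {
    stop("unknown parameter(s) for agent kind '", kind, "': ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  params <- utils::modifyList(defaults, params)
  check_prob <- function(name, lo = 0, hi = 1, lo_open = FALSE,
                         hi_open = FALSE) {
    v <- params[[name]]
    bad <- !(is.numeric(v) && length(v) == 1L && is.finite(v)) ||
      (if (lo_open) v <= lo else v < lo) ||
      (if (hi_open) v >= hi else v > hi)
    if (bad) {
      stop("invalid agent parameter `", name, "`: must be a number in ",
           if (lo_open) "(" else "[", lo, ", ", hi,
           if (hi_open) ")" else "]", call. = FALSE)
    }
  }
  switch(kind,
    bernoulli = check_prob("p_plus"),
    wsls = {
      check_prob("stay_reward")
      check_prob("shift_noreward")
    },
    qlearn = {
      check_prob("alpha", lo = 0, lo_open = TRUE)
      check_prob("epsilon")
      check_prob("q0_plus", lo = -Inf, hi = Inf)
      check_prob("q0_minus", lo = -Inf, hi = Inf)
    },
    regularity_seeker = {
      check_prob("commitment_gain", lo = 0, lo_open = TRUE)
      check_prob("exploration_floor", hi = 0.5, hi_open = TRUE)
      check_prob("commit_init")
    },
    NULL
  )
  params
}

#' @export
print.racas_agent_spec <- function(x, ...) {
  cat("<racas_agent_spec>", agent_label(x), "seed", x$seed, "\n")
  invisible(x)
}

#' Human-readable label for an agent specification
#'
#' @param spec A `racas_agent_spec`.
#' @return A string such as `"bernoulli(p_plus=0.5)"`.
#' @export
agent_label <- function(spec) {
  stopifnot(inherits(spec, "racas_agent_spec"))
  if (length(spec$params) == 0L) return(spec$kind)
  p <- vapply(spec$params, function(v) format(v, digits = 6), character(1))
  paste0(spec$kind, "(", paste(names(p), p, sep = "=", collapse = ","), ")")
}

# -- private random streams ---------------------------------------------------

# Capture a fresh .Random.seed for `seed` without disturbing the caller's
# global stream.
rng_make <- function(seed) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(rng_restore(old), add = TRUE)
  set.seed(seed)
  get(".Random.seed", envir = globalenv(), inherits = FALSE)
}

rng_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

# Evaluate fn() under the agent's private stream; returns list(result, state)
# with the advanced stream stored back into the state.
rng_eval <- function(state, fn) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  assign(".Random.seed", state$rng, envir = globalenv())
  result <- fn()
  state$rng <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  rng_restore(old)
  list(result = result, state = state)
}

# -- agent lifecycle ----------------------------------------------------------

#' Initialize an agent's state
#'
#' @param spec A `racas_agent_spec`.
#' @param seed Seed of the agent's private random stream; defaults to the
#'   seed recorded in the spec. Initialization is a deterministic function
#'   of `(spec, seed)`.
#' @return An object of classes `racas_agent_<kind>` and `racas_agent`.
#' @export
agent_init <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "racas_agent_spec"))
  state <- list(spec = spec, rng = rng_make(seed))
  state <- c(state, switch(spec$kind,
    wsls = list(last_choice = NA_character_, last_obtained = NA),
    qlearn = list(q = c(P = spec$params$q0_plus, M = spec$params$q0_minus)),
    regularity_seeker = list(
      commit_p = spec$params$commit_init,
      expected_gap = NA_integer_,
      clicks_since_reward = 0L
    ),
    list()
  ))
  class(state) <- c(paste0("racas_agent_", spec$kind), "racas_agent")
  state
}

#' Ask an agent for its next choice
#'
#' Stochastic agents draw from their private stream only; the caller's
#' global random state is left untouched.
#'
#' @param state An agent state from [agent_init()] or [agent_update()].
#' @return A list with `choice` (`"P"` or `"M"`) and the updated `state`
#'   (the private stream advances on stochastic kinds).
#' @export
agent_choose <- function(state) {
  stopifnot(inherits(state, "racas_agent"))
  rng_eval_state(state, choose_impl)
}

# Evaluate fn(state) -> list(choice, state) under the agent's private
# stream, storing the advanced stream back into the returned state.
rng_eval_state <- function(state, fn) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  assign(".Random.seed", state$rng, envir = globalenv())
  out <- fn(state)
  out$state$rng <- get(".Random.seed", envir = globalenv(),
                       inherits = FALSE)
  rng_restore(old)
  out
}

# Kind-specific choice rule; draws from the RNG stream currently installed
# in the session (agent_choose and run_session arrange for that stream to
# be the agent's private one).
choose_impl <- function(state) UseMethod("choose_impl")

#' @export
choose_impl.racas_agent_always_plus <- function(state) {
  list(choice = SIDE_PLUS, state = state)
}

#' @export
choose_impl.racas_agent_always_minus <- function(state) {
  list(choice = SIDE_MINUS, state = state)
}

#' @export
choose_impl.racas_agent_bernoulli <- function(state) {
  choice <- if (stats::runif(1) < state$spec$params$p_plus) SIDE_PLUS
            else SIDE_MINUS
  list(choice = choice, state = state)
}

#' @export
choose_impl.racas_agent_wsls <- function(state) {
  p <- state$spec$params
  u <- stats::runif(1)
  choice <- if (is.na(state$last_choice)) {
    if (u < 0.5) SIDE_PLUS else SIDE_MINUS
  } else {
    other <- if (state$last_choice == SIDE_PLUS) SIDE_MINUS else SIDE_PLUS
    if (isTRUE(state$last_obtained)) {
      if (u < p$stay_reward) state$last_choice else other
    } else {
      if (u < p$shift_noreward) other else state$last_choice
    }
  }
  list(choice = choice, state = state)
}

#' @export
choose_impl.racas_agent_qlearn <- function(state) {
  q <- state$q
  explore <- stats::runif(1) < state$spec$params$epsilon
  choice <- if (explore || q[["P"]] == q[["M"]]) {
    # exploration, or greedy tie: pick a side uniformly
    if (stats::runif(1) < 0.5) SIDE_PLUS else SIDE_MINUS
  } else if (q[["P"]] > q[["M"]]) SIDE_PLUS else SIDE_MINUS
  list(choice = choice, state = state)
}

#' @export
choose_impl.racas_agent_regularity_seeker <- function(state) {
  p <- state$spec$params
  prob <- min(max(state$commit_p, p$exploration_floor),
              1 - p$exploration_floor)
  choice <- if (stats::runif(1) < prob) SIDE_PLUS else SIDE_MINUS
  list(choice = choice, state = state)
}

#' Update an agent on the outcome of its own choice
#'
#' @param state The agent state that produced `choice`.
#' @param choice The side chosen (`"P"` or `"M"`).
#' @param obtained Logical; whether a reward was obtained on that choice.
#' @return The updated agent state.
#' @export
agent_update <- function(state, choice, obtained) UseMethod("agent_update")

#' @export
agent_update.racas_agent <- function(state, choice, obtained) {
  state # memoryless kinds: always_plus, always_minus, bernoulli
}

#' @export
agent_update.racas_agent_wsls <- function(state, choice, obtained) {
  state$last_choice <- choice
  state$last_obtained <- isTRUE(obtained)
  state
}

#' @export
agent_update.racas_agent_qlearn <- function(state, choice, obtained) {
  a <- state$spec$params$alpha
  r <- as.numeric(isTRUE(obtained))
  state$q[choice] <- state$q[choice] + a * (r - state$q[choice])
  state
}

#' @export
agent_update.racas_agent_regularity_seeker <- function(state, choice,
                                                       obtained) {
  g <- state$spec$params$commitment_gain
  if (choice == SIDE_PLUS) {
    state$clicks_since_reward <- state$clicks_since_reward + 1L
    if (isTRUE(obtained)) {
      gap <- state$clicks_since_reward
      if (!is.na(state$expected_gap) &&
          gap %in% c(state$expected_gap, state$expected_gap + 1L)) {
        # the widening-interval hypothesis was confirmed
        state$commit_p <- state$commit_p + g * (1 - state$commit_p)
      }
      state$expected_gap <- gap
      state$clicks_since_reward <- 0L
    } else if (!is.na(state$expected_gap) &&
               state$clicks_since_reward > state$expected_gap + 1L) {
      # reward overdue under the hypothesized pattern
      state$commit_p <- state$commit_p - g * state$commit_p
    }
  } else {
    # defection breaks the tracked pattern; a reward found on Bias- argues
    # against commitment
    state$expected_gap <- NA_integer_
    state$clicks_since_reward <- 0L
    if (isTRUE(obtained)) {
      state$commit_p <- state$commit_p - g * state$commit_p
    }
  }
  state
}
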