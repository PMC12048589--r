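# Canonical session CSV, the external-export adapter, and fixture
# generation. One row per trial; sides coded "P" (Bias+) and "M" (Bias-);
# flags coded 0/1. Files round-trip losslessly and every read is validated
# against the task invariants with row-addressed errors.

SESSION_COLUMNS <- c("session_id", "trial", "choice", "alloc_plus",
                     "alloc_minus", "obtained", "agent", "seed")

session_col_types <- function() {
  readr::cols(
    session_id = readr::col_character(),
    trial = readr::col_integer(),
    choice = readr::col_character(),
    alloc_plus = readr::col_integer(),
    alloc_minus = readr::col_integer(),
    obtained = readr::col_integer(),
    agent = readr::col_character(),
    seed = readr::col_integer()
  )
}

#' Convert sessions to one long table
#'
#' @param results A `racas_session` or list of them.
#' @return A tibble with the canonical columns `session_id`, `trial`,
#'   `choice`, `alloc_plus`, `alloc_minus`, `obtained`, `agent`, `seed`
#'   (flags coded 0/1), ordered by session then trial. Sessions without an
#'   id are numbered `s0001`, `s0002`, ... in order.
#' @export
sessions_to_table <- function(results) {
  if (inherits(results, "racas_session")) results <- list(results)
  if (length(results) == 0L) {
    return(tibble::tibble(
      session_id = character(0), trial = integer(0), choice = character(0),
      alloc_plus = integer(0), alloc_minus = integer(0),
      obtained = integer(0), agent = character(0), seed = integer(0)
    ))
  }
  stopifnot(all(vapply(results, inherits, logical(1), "racas_session")))
  rows <- lapply(seq_along(results), function(k) {
    s <- results[[k]]
    r <- s$records
    tibble::tibble(
      session_id = s$session_id %||% sprintf("s%04d", k),
      trial = as.integer(r$trial),
      choice = r$choice,
      alloc_plus = as.integer(r$alloc_plus),
      alloc_minus = as.integer(r$alloc_minus),
      obtained = as.integer(r$obtained),
      agent = s$agent,
      seed = s$seed
    )
  })
  do.call(rbind, rows)
}

#' Write sessions to the canonical CSV
#'
#' @param results A `racas_session` or list of them (may be empty: a
#'   header-only file is written).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sessions <- function(results, path) {
  readr::write_csv(sessions_to_table(results), path)
  invisible(path)
}

# Rebuild racas_session objects from a validated canonical table.
table_to_sessions <- function(tab) {
  ids <- unique(tab$session_id)
  lapply(ids, function(id) {
    r <- tab[tab$session_id == id, , drop = FALSE]
    r <- r[order(r$trial), , drop = FALSE]
    session <- structure(
      list(
        records = tibble::tibble(
          trial = as.integer(r$trial),
          choice = r$choice,
          alloc_plus = as.logical(r$alloc_plus),
          alloc_minus = as.logical(r$alloc_minus),
          obtained = as.logical(r$obtained)
        ),
        agent = r$agent[1],
        agent_spec = NULL,
        seed = r$seed[1],
        session_id = id
      ),
      class = "racas_session"
    )
    validate_session(session, id = id)
    session
  })
}

validate_table_shape <- function(tab, path) {
  missing <- setdiff(SESSION_COLUMNS, names(tab))
  if (length(missing) > 0L) {
    stop("'", path, "': missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  for (col in c("alloc_plus", "alloc_minus", "obtained")) {
    bad <- which(!(tab[[col]] %in% c(0L, 1L)))
    if (length(bad) > 0L) {
      stop("session '", tab$session_id[bad[1]], "', trial ",
           tab$trial[bad[1]], ": `", col, "` must be 0 or 1",
           call. = FALSE)
    }
  }
  invisible(tab)
}

#' Read sessions from the canonical CSV
#'
#' Every session is validated: exactly 100 trials numbered 1..100, choices
#' in {P, M}, 25 allocations per side, and `obtained` equal to the
#' allocation on the chosen side. Violations raise errors naming the
#' session and trial.
#'
#' @param path CSV written by [write_sessions()] (or conforming to its
#'   schema).
#' @return A list of `racas_session` objects.
#' @export
read_sessions <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  header <- names(readr::read_csv(path, n_max = 0,
                                  col_types = readr::cols(.default = "c")))
  missing <- setdiff(SESSION_COLUMNS, header)
  if (length(missing) > 0L) {
    stop("'", path, "': missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  tab <- readr::read_csv(path, col_types = session_col_types())
  prob <- readr::problems(tab)
  if (nrow(prob) > 0L) {
    stop("'", path, "': ", nrow(prob), " malformed cell(s); first at row ",
         prob$row[1], ": ", prob$expected[1], call. = FALSE)
  }
  validate_table_shape(tab, path)
  table_to_sessions(tab)
}

#' Read an external per-trial export via a column mapping
#'
#' Adapter for third-party exports of the same task (per-trial records of
#' choice side, per-side allocation, and obtained reward). The export's
#' schema is supplied as a mapping rather than hard-coded, so differently
#' named or differently coded files normalize to the canonical form.
#'
#' @param path CSV file to read.
#' @param mapping Named list giving, for each canonical field, the source
#'   column name: `session_id`, `trial`, `choice`, `alloc_plus`,
#'   `alloc_minus`, `obtained` (required); `agent`, `seed` (optional).
#'   Plus the choice coding: `plus_label` and `minus_label`, the values in
#'   the source choice column meaning Bias+ and Bias- (required; defaults
#'   `"P"`/`"M"` give the identity mapping on canonical files).
#' @return A list of validated `racas_session` objects. Rows that cannot
#'   be normalized (unknown choice codes, non-binary flags, inconsistent
#'   outcomes) raise errors naming the session and trial.
#' @export
read_cec_export <- function(path,
                            mapping = list(plus_label = "P",
                                           minus_label = "M")) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  defaults <- list(session_id = "session_id", trial = "trial",
                   choice = "choice", alloc_plus = "alloc_plus",
                   alloc_minus = "alloc_minus", obtained = "obtained",
                   plus_label = "P", minus_label = "M")
  unknown <- setdiff(names(mapping),
                     c(names(defaults), "agent", "seed"))
  if (length(unknown) > 0L) {
    stop("unknown mapping field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  mapping <- utils::modifyList(defaults, mapping)

  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"))
  src_cols <- unlist(mapping[c("session_id", "trial", "choice",
                               "alloc_plus", "alloc_minus", "obtained")])
  if (!is.null(mapping$agent)) src_cols <- c(src_cols, mapping$agent)
  if (!is.null(mapping$seed)) src_cols <- c(src_cols, mapping$seed)
  missing <- setdiff(unname(src_cols), names(raw))
  if (length(missing) > 0L) {
    stop("'", path, "': mapping refers to missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }

  choice_raw <- raw[[mapping$choice]]
  known <- choice_raw %in% c(mapping$plus_label, mapping$minus_label)
  if (!all(known)) {
    bad <- which(!known)[1]
    stop("'", path, "' row ", bad, ": unrecognized choice code '",
         choice_raw[bad], "' (expected '", mapping$plus_label, "' or '",
         mapping$minus_label, "')", call. = FALSE)
  }

  tab <- tibble::tibble(
    session_id = raw[[mapping$session_id]],
    trial = suppressWarnings(as.integer(raw[[mapping$trial]])),
    choice = ifelse(choice_raw == mapping$plus_label, SIDE_PLUS, SIDE_MINUS),
    alloc_plus = suppressWarnings(as.integer(raw[[mapping$alloc_plus]])),
    alloc_minus = suppressWarnings(as.integer(raw[[mapping$alloc_minus]])),
    obtained = suppressWarnings(as.integer(raw[[mapping$obtained]])),
    agent = if (is.null(mapping$agent)) "external"
            else raw[[mapping$agent]],
    seed = if (is.null(mapping$seed)) NA_integer_
           else suppressWarnings(as.integer(raw[[mapping$seed]]))
  )
  if (anyNA(tab$trial)) {
    bad <- which(is.na(tab$trial))[1]
    stop("'", path, "' row ", bad, ": non-integer trial index",
         call. = FALSE)
  }
  validate_table_shape(tab, path)
  table_to_sessions(tab)
}

FIXTURE_SCENARIOS <- c("always_plus", "always_minus", "alternating",
                       "random", "strong_bias", "medium_bias", "weak_bias")

#' Generate named fixture sessions
#'
#' Deterministic single-session fixtures for tests and documentation:
#' the two degenerate policies, a strict alternator, a fair coin, and
#' three regularity-seeker settings spanning strong, medium, and weak
#' commitment to the Bias+ side.
#'
#' @param kind One of `"always_plus"`, `"always_minus"`, `"alternating"`,
#'   `"random"`, `"strong_bias"`, `"medium_bias"`, `"weak_bias"`.
#' @param seed Seed for the scenario's agent.
#' @return A list containing one `racas_session`.
#' @export
make_fixtures <- function(kind, seed = 1L) {
  if (!(is.character(kind) && length(kind) == 1L &&
        kind %in% FIXTURE_SCENARIOS)) {
    stop("unknown scenario '", paste(kind, collapse = ","),
         "'; known scenarios: ", paste(FIXTURE_SCENARIOS, collapse = ", "),
         call. = FALSE)
  }
  spec <- switch(kind,
    always_plus  = agent_spec("always_plus", seed = seed),
    always_minus = agent_spec("always_minus", seed = seed),
    alternating  = agent_spec("wsls", list(stay_reward = 0,
                                           shift_noreward = 1), seed = seed),
    random       = agent_spec("bernoulli", list(p_plus = 0.5), seed = seed),
    strong_bias  = agent_spec("regularity_seeker",
                              list(commitment_gain = 0.5,
                                   exploration_floor = 0.02,
                                   commit_init = 0.8), seed = seed),
    medium_bias  = agent_spec("regularity_seeker",
                              list(commitment_gain = 0.25,
                                   exploration_floor = 0.1,
                                   commit_init = 0.6), seed = seed),
    weak_bias    = agent_spec("regularity_seeker",
                              list(commitment_gain = 0.1,
                                   exploration_floor = 0.3,
                                   commit_init = 0.5), seed = seed)
  )
  list(run_session(spec, seed = seed, session_id = paste0(kind, "_1")))
}
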