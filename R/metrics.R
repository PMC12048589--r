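# Per-session and group-level behavioral statistics: choice bias, the
# normalized reward difference, observed expectancy, exploitation, rolling
# averages, Cohen's d, classical t machinery, and Spearman rank correlation.
# Undefined ratios (0/0, e.g. a side never chosen) are NA_real_, never 0.

#' Fraction of Bias+ choices in a session
#'
#' @param session A `racas_session`.
#' @return Fraction of the 100 trials on which Bias+ was chosen, in
#'   \[0, 1\].
#' @export
bias_fraction <- function(session) {
  stopifnot(inherits(session, "racas_session"))
  mean(session$records$choice == SIDE_PLUS)
}

#' Normalized reward difference between sides
#'
#' `(R+ - R-) / (R+ + R-)` over *obtained* rewards: +1 when every reward
#' collected came from the Bias+ side, -1 when every one came from Bias-,
#' 0 when collection was balanced.
#'
#' @param session A `racas_session`.
#' @return A value in \[-1, 1\], or `NA_real_` when no reward was obtained.
#' @export
delta_rewards_norm <- function(session) {
  stopifnot(inherits(session, "racas_session"))
  r <- session$records
  rp <- sum(r$obtained & r$choice == SIDE_PLUS)
  rm_ <- sum(r$obtained & r$choice == SIDE_MINUS)
  if (rp + rm_ == 0L) return(NA_real_)
  (rp - rm_) / (rp + rm_)
}

#' Observed expectancy of a side
#'
#' Rewards obtained when selecting an option, divided by the number of
#' times that option was chosen: the agent's empirical payoff rate per
#' option.
#'
#' @param session A `racas_session`.
#' @param side `"P"` or `"M"`.
#' @return A fraction in \[0, 1\], or `NA_real_` when the side was never
#'   chosen.
#' @export
observed_expectancy <- function(session, side) {
  stopifnot(inherits(session, "racas_session"))
  side <- match.arg(side, c(SIDE_PLUS, SIDE_MINUS))
  r <- session$records
  n_chosen <- sum(r$choice == side)
  if (n_chosen == 0L) return(NA_real_)
  sum(r$obtained & r$choice == side) / n_chosen
}

#' Exploitation of a side's allocated rewards
#'
#' Rewards obtained on an option divided by the rewards allocated to it
#' (25 in a complete session): the fraction of the available rewards the
#' agent discovered.
#'
#' @param session A complete `racas_session` (25 allocations per side).
#' @param side `"P"` or `"M"`.
#' @return A fraction in \[0, 1\].
#' @export
exploitation <- function(session, side) {
  stopifnot(inherits(session, "racas_session"))
  side <- match.arg(side, c(SIDE_PLUS, SIDE_MINUS))
  r <- session$records
  alloc <- if (side == SIDE_PLUS) r$alloc_plus else r$alloc_minus
  if (sum(alloc) != REWARDS_PER_SIDE) {
    stop("incomplete session: side ", side, " has ", sum(alloc),
         " allocations, expected 25", call. = FALSE)
  }
  sum(r$obtained & r$choice == side) / REWARDS_PER_SIDE
}

#' Summarize one session's behavioral metrics
#'
#' @param session A `racas_session`.
#' @return A one-row tibble with `session_id`, `agent`, `seed`,
#'   `bias_plus`, `delta_rewards_norm`, `expectancy_plus`,
#'   `expectancy_minus`, `exploitation_plus`, `exploitation_minus`, and
#'   `total_obtained`.
#' @export
session_metrics <- function(session) {
  stopifnot(inherits(session, "racas_session"))
  tibble::tibble(
    session_id = session$session_id %||% NA_character_,
    agent = session$agent,
    seed = session$seed,
    bias_plus = bias_fraction(session),
    delta_rewards_norm = delta_rewards_norm(session),
    expectancy_plus = observed_expectancy(session, SIDE_PLUS),
    expectancy_minus = observed_expectancy(session, SIDE_MINUS),
    exploitation_plus = exploitation(session, SIDE_PLUS),
    exploitation_minus = exploitation(session, SIDE_MINUS),
    total_obtained = sum(session$records$obtained)
  )
}

#' Summarize a list of sessions
#'
#' @param sessions A list of `racas_session` objects.
#' @return A tibble with one [session_metrics()] row per session.
#' @export
summarize_sessions <- function(sessions) {
  if (inherits(sessions, "racas_session")) sessions <- list(sessions)
  do.call(rbind, lapply(sessions, session_metrics))
}

#' Trailing rolling mean
#'
#' Windowed mean with a trailing window and the warm-up trimmed: the
#' result has `length(series) - window + 1` values, the i-th averaging
#' positions `i .. i+window-1`.
#'
#' @param series Numeric vector.
#' @param window Window size, an integer in `1..length(series)`
#'   (default 10).
#' @return Numeric vector of length `length(series) - window + 1`.
#' @export
rolling_mean <- function(series, window = 10L) {
  if (!(length(window) == 1L && !is.na(window) &&
        window == as.integer(window) && window >= 1L)) {
    stop("`window` must be a positive integer", call. = FALSE)
  }
  if (window > length(series)) {
    stop("`window` (", window, ") exceeds series length (", length(series),
         ")", call. = FALSE)
  }
  as.numeric(zoo::rollmean(as.numeric(series), k = window, align = "right"))
}

#' One-sample Cohen's d
#'
#' Standardized mean difference `(mean(values) - mu0) / sd(values)` with
#' the sample (n-1) standard deviation.
#'
#' @param values Numeric vector of length >= 2 with positive variance.
#' @param mu0 Reference value.
#' @return Signed effect size.
#' @export
cohens_d_one_sample <- function(values, mu0) {
  if (length(values) < 2L) {
    stop("need at least 2 values", call. = FALSE)
  }
  s <- stats::sd(values)
  if (!is.finite(s) || s == 0) {
    stop("degenerate input: zero variance", call. = FALSE)
  }
  (mean(values) - mu0) / s
}

#' One- or two-sample comparison of means
#'
#' Classical Student t machinery (two-tailed; pooled variance for the
#' two-sample case) plus the matching Cohen's d: one-sample d uses the
#' sample SD against `mu0`, two-sample d uses the pooled SD.
#'
#' @param a Numeric vector (>= 2 values).
#' @param b Optional second sample; when `NULL` a one-sample test of
#'   `mean(a) == mu0` is performed.
#' @param mu0 Null value for the one-sample test (default 0).
#' @return A list with `t`, `df`, `p` (two-tailed), `ci` (95% CI of the
#'   mean difference), `d`, and `estimate` (mean of `a`, or mean
#'   difference).
#' @export
group_compare <- function(a, b = NULL, mu0 = 0) {
  if (length(a) < 2L || (!is.null(b) && length(b) < 2L)) {
    stop("need at least 2 values per sample", call. = FALSE)
  }
  if (is.null(b)) {
    if (stats::sd(a) == 0) {
      stop("degenerate input: zero variance", call. = FALSE)
    }
    tt <- stats::t.test(a, mu = mu0)
    d <- cohens_d_one_sample(a, mu0)
    est <- mean(a)
  } else {
    n1 <- length(a); n2 <- length(b)
    sp2 <- ((n1 - 1) * stats::var(a) + (n2 - 1) * stats::var(b)) /
      (n1 + n2 - 2)
    if (!is.finite(sp2) || sp2 == 0) {
      stop("degenerate input: zero pooled variance", call. = FALSE)
    }
    tt <- stats::t.test(a, b, var.equal = TRUE)
    d <- (mean(a) - mean(b)) / sqrt(sp2)
    est <- mean(a) - mean(b)
  }
  list(
    t = unname(tt$statistic),
    df = unname(tt$parameter),
    p = tt$p.value,
    ci = unname(tt$conf.int),
    d = d,
    estimate = est
  )
}

#' Spearman rank correlation
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return A list with `rho` in \[-1, 1\] and the two-tailed `p` value
#'   (asymptotic, so tied ranks are handled).
#' @export
rank_correlation <- function(x, y) {
  if (length(x) != length(y)) {
    stop("`x` and `y` must have equal lengths", call. = FALSE)
  }
  if (length(x) < 3L) {
    stop("need at least 3 paired observations", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "spearman", exact = FALSE)
  list(rho = unname(ct$estimate), p = ct$p.value)
}
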