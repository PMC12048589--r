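# Behavioral metrics and the statistics layer.

# A hand-built valid session with no obtained reward at all: rewards sit on
# whichever side the agent did not choose.
zero_obtained_session <- function() {
  structure(
    list(
      records = tibble::tibble(
        trial = 1:100,
        choice = rep(c("M", "P"), c(25, 75)),
        alloc_plus = c(rep(TRUE, 25), rep(FALSE, 75)),
        alloc_minus = c(rep(FALSE, 25), rep(TRUE, 25), rep(FALSE, 50)),
        obtained = rep(FALSE, 100)
      ),
      agent = "constructed", agent_spec = NULL, seed = NA_integer_,
      session_id = "zero"
    ),
    class = "racas_session"
  )
}

test_that("bias_fraction counts Bias+ choices over all 100 trials", {
  expect_equal(bias_fraction(make_session("always_plus")), 1)
  expect_equal(bias_fraction(make_session("always_minus")), 0)
  s <- zero_obtained_session()
  s$records$choice <- rep(c("P", "M"), c(70, 30))
  expect_equal(bias_fraction(s), 0.7)
})

test_that("delta_rewards_norm spans [-1, 1] with an explicit NA for 0/0", {
  expect_equal(delta_rewards_norm(make_session("always_plus")), 1)
  expect_equal(delta_rewards_norm(make_session("always_minus")), -1)
  expect_identical(delta_rewards_norm(zero_obtained_session()), NA_real_)

  # R+ = 15, R- = 5 -> (15 - 5) / 20 = 0.5. Choices alternate P on odd
  # trials, M on even; collected rewards sit on chosen trials, the budget
  # remainder on unchosen ones.
  s <- zero_obtained_session()
  s$records$choice <- rep(c("P", "M"), 50)
  s$records$alloc_plus <- s$records$trial %in% c(seq(1, 29, 2),   # 15 found
                                                 seq(52, 70, 2))  # 10 missed
  s$records$alloc_minus <- s$records$trial %in% c(seq(2, 10, 2),  # 5 found
                                                  seq(51, 89, 2)) # 20 missed
  s$records$obtained <- ifelse(s$records$choice == "P",
                               s$records$alloc_plus, s$records$alloc_minus)
  expect_equal(sum(s$records$obtained & s$records$choice == "P"), 15L)
  expect_equal(sum(s$records$obtained & s$records$choice == "M"), 5L)
  expect_equal(delta_rewards_norm(s), 0.5)
})

test_that("observed expectancy is rewards per choice of that side", {
  s <- make_session("always_plus")
  expect_equal(observed_expectancy(s, "P"), 0.25) # 25 rewards / 100 choices
  expect_identical(observed_expectancy(s, "M"), NA_real_) # never chosen
})

test_that("exploitation is the fraction of a side's 25 rewards found", {
  s <- make_session("always_plus")
  expect_equal(exploitation(s, "P"), 1)
  expect_equal(exploitation(s, "M"), 0)
  s$records <- s$records[1:80, ] # truncated: < 25 allocations on each side
  expect_error(exploitation(s, "P"), "incomplete")
})

test_that("metric identities hold on every simulated session", {
  withr::with_seed(31, {
    for (spec in sweep_specs()) {
      s <- run_session(spec, seed = sample.int(100000, 1))
      r <- s$records
      obtained_plus <- sum(r$obtained & r$choice == "P")
      choices_plus <- sum(r$choice == "P")
      ep <- observed_expectancy(s, "P")
      if (choices_plus > 0) {
        expect_equal(obtained_plus, ep * choices_plus)
      }
      expect_equal(obtained_plus, exploitation(s, "P") * 25)
      d <- delta_rewards_norm(s)
      if (!is.na(d)) expect_true(d >= -1 && d <= 1)
      b <- bias_fraction(s)
      expect_true(b >= 0 && b <= 1)
      m <- session_metrics(s)
      expect_equal(m$total_obtained, sum(r$obtained))
    }
  })
})

test_that("rolling_mean uses a trailing window with trimmed warm-up", {
  expect_equal(rolling_mean(rep(1, 20), 10), rep(1, 11))
  expect_equal(rolling_mean(rep(c(0, 1), 10), 2), rep(0.5, 19))
  expect_equal(rolling_mean(c(3, 1, 4, 1, 5), 1), c(3, 1, 4, 1, 5))
  x <- c(1, 2, 6, 2, 9, 3)
  expect_equal(rolling_mean(x, 3), c(3, 10 / 3, 17 / 3, 14 / 3))
  # commutes with affine transforms
  expect_equal(rolling_mean(2 * x + 5, 3), 2 * rolling_mean(x, 3) + 5)
  expect_error(rolling_mean(1:5, 6), "exceeds")
  expect_error(rolling_mean(1:5, 0), "positive integer")
})

test_that("one-sample Cohen's d uses the sample SD", {
  expect_equal(cohens_d_one_sample(c(0.6, 0.8), 0.5),
               0.2 / sd(c(0.6, 0.8)))
  expect_equal(round(cohens_d_one_sample(c(0.6, 0.8), 0.5), 4), 1.4142)
  expect_equal(cohens_d_one_sample(c(1, 2, 3), 2), 0)
  expect_error(cohens_d_one_sample(c(1, 1, 1), 0), "zero variance")
  expect_error(cohens_d_one_sample(1, 0), "at least 2")
})

test_that("group_compare matches textbook closed forms", {
  # identical samples: no difference
  res <- group_compare(c(1, 2, 3), c(1, 2, 3))
  expect_equal(res$t, 0)
  expect_equal(res$p, 1)
  expect_equal(res$d, 0)

  # one-sample, 2 elements, by hand: t = (mean - mu0) / (sd / sqrt(2))
  a <- c(1, 3)
  res1 <- group_compare(a, mu0 = 1)
  expect_equal(res1$t, (mean(a) - 1) / (sd(a) / sqrt(2)))
  expect_equal(res1$df, 1)
  expect_equal(res1$p, 2 * pt(-abs(res1$t), df = 1))

  # two-sample, 2 elements each, pooled-variance Student formulas
  b <- c(2, 4); c_ <- c(1, 2)
  sp2 <- (var(b) + var(c_)) / 2
  t_exp <- (mean(b) - mean(c_)) / sqrt(sp2 * (1 / 2 + 1 / 2))
  res2 <- group_compare(b, c_)
  expect_equal(res2$t, t_exp)
  expect_equal(res2$df, 2)
  expect_equal(res2$p, 2 * pt(-abs(t_exp), df = 2))
  expect_equal(res2$d, (mean(b) - mean(c_)) / sqrt(sp2))

  expect_error(group_compare(c(2, 2, 2), mu0 = 2), "zero variance")
  expect_error(group_compare(c(1, 1), c(2, 2)), "zero pooled variance")
})

test_that("rank correlation recovers monotone relations", {
  x <- c(1, 2, 3, 5, 8)
  expect_equal(rank_correlation(x, x)$rho, 1)
  expect_equal(rank_correlation(x, -x)$rho, -1)
  expect_equal(rank_correlation(c(1, 2, 3), c(2, 1, 3))$rho, 0.5)
  expect_error(rank_correlation(1:4, 1:5), "equal lengths")
  expect_error(rank_correlation(1:2, 2:1), "at least 3")
})

test_that("session summaries collect all per-session metrics", {
  batch <- run_experiment(list(agent_spec("always_plus"),
                               agent_spec("bernoulli")),
                          n_per_spec = 2, base_seed = 3)
  tab <- summarize_sessions(batch)
  expect_equal(nrow(tab), 4L)
  expect_equal(tab$bias_plus[1:2], c(1, 1))
  expect_equal(tab$exploitation_plus[1:2], c(1, 1))
  expect_equal(tab$total_obtained[1:2], c(25L, 25L))
  gs <- group_stats(tab)
  expect_equal(sort(gs$group),
               sort(unique(tab$agent)))
  expect_equal(gs$n, c(2L, 2L))
})
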