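test_that("requirement formula reproduces the printed schedule and keeps growing", {
  expect_identical(pr_requirement(1:18), printed_pr_schedule)
  expect_equal(pr_requirement(10), 32)
  seq50 <- pr_requirement(1:50)
  expect_true(all(diff(seq50) > 0))
  expect_error(pr_requirement(0), class = "addix_domain_error")
  expect_identical(pr_requirement(integer()), integer())
})

test_that("breakpoint follows the 60-min termination rule on worked examples", {
  expect_equal(compute_breakpoint(pr_session_log(numeric())),
               list(n_rewards = 0L, breakpoint = 0L))
  expect_equal(compute_breakpoint(pr_session_log(c(2, 9, 20, 45))),
               list(n_rewards = 4L, breakpoint = 6L))
  # 18 rewards every 15 min: trailing 90-min silence ends the session but
  # keeps all completions
  expect_equal(compute_breakpoint(generate_pr_event_log(18, 15)),
               list(n_rewards = 18L, breakpoint = 178L))
  # 60-min silence before the first reward terminates with nothing earned
  expect_equal(compute_breakpoint(pr_session_log(c(60, 70))),
               list(n_rewards = 0L, breakpoint = 0L))
  # an interior gap cuts the count at the gap
  expect_equal(compute_breakpoint(pr_session_log(c(10, 30, 95, 100))),
               list(n_rewards = 2L, breakpoint = 2L))
  expect_error(pr_session_log(c(10, 5)), class = "addix_data_error")
})

test_that("breakpoint matches a literal prefix-enumeration oracle on random logs", {
  set.seed(7)
  for (i in 1:1000) {
    n <- sample(0:25, 1)
    times <- sort(round(runif(n, 0, 360), 1))
    times <- unique(times)
    got <- compute_breakpoint(pr_session_log(times))
    want <- oracle_breakpoint(times)
    expect_identical(got, want)
  }
})

test_that("appending a reward within 60 min never decreases the breakpoint", {
  set.seed(8)
  for (i in 1:200) {
    n <- sample(1:15, 1)
    times <- sort(runif(n, 0, 290))
    times <- unique(times)
    base <- compute_breakpoint(pr_session_log(times))
    extra <- min(tail(times, 1) + runif(1, 0.1, 59.9), 360)
    grown <- compute_breakpoint(pr_session_log(c(times, extra)))
    expect_gte(grown$n_rewards, base$n_rewards)
    expect_gte(grown$breakpoint, base$breakpoint)
  }
})

test_that("event-log fixtures feed the breakpoint rule as designed", {
  expect_equal(generate_pr_event_log(0, 10)$n_rewards, 0)
  log4 <- generate_pr_event_log(4, 10)
  expect_equal(compute_breakpoint(log4), list(n_rewards = 4L, breakpoint = 6L))
  expect_error(generate_pr_event_log(10, 40, session_minutes = 360),
               class = "addix_config_error")
  # CSV round trip
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(reward_index = 1:4,
                                  minutes = log4$reward_times), path)
  expect_equal(compute_breakpoint(read_pr_event_log(path)),
               list(n_rewards = 4L, breakpoint = 6L))
})

test_that("escalation summary averages the last three extended-access days", {
  expect_equal(escalation_summary(rep(60, 14)), 60)
  expect_equal(escalation_summary(c(rep(40, 11), 80, 90, 100)), 90)
  # gap on day 13 imputed from neighbors, then averaged
  vals <- c(rep(40, 11), 80, NA, 100)
  filled <- impute_missing_sessions(vals)$values
  expect_equal(escalation_summary(filled), 90)
  # unresolved trailing gap poisons the summary
  expect_true(is.na(escalation_summary(c(rep(40, 13), NA))))
})

test_that("hourly rate converts session totals, matching the resilience threshold", {
  expect_equal(round(hourly_rate(50, 6)), 8)  # <50/session ~ 8 infusions/hr
  expect_equal(hourly_rate(16, 2), 8)
  expect_equal(hourly_rate(0, 6), 0)
  expect_error(hourly_rate(10, 0), class = "addix_domain_error")
})

test_that("irritability assay scores average observers and sum components", {
  rec <- irritability_scores(c(2, 3, 4), c(1, 1, 1))
  expect_equal(rec$aggressive, 3)
  expect_equal(rec$defensive, 1)
  expect_equal(rec$total, 4)
  expect_equal(irritability_scores(0, 0)$total, 0)
  one <- irritability_scores(5, 2)
  expect_equal(c(one$aggressive, one$defensive, one$total), c(5, 2, 7))
  expect_error(irritability_scores(c(2, -1), c(0, 0)),
               class = "addix_data_error")
  # total == aggressive + defensive holds for arbitrary observer panels
  set.seed(3)
  for (i in 1:20) {
    k <- sample(1:4, 1)
    r <- irritability_scores(runif(k, 0, 10), runif(k, 0, 10))
    expect_equal(r$total, r$aggressive + r$defensive)
  }
})

test_that("irritability delta subtracts baseline componentwise", {
  b <- irritability_scores(3, 2, rat_id = "A", timepoint = "baseline")
  w <- irritability_scores(6, 3, rat_id = "A", timepoint = "withdrawal")
  expect_equal(irritability_delta(b, w),
               list(aggressive = 3, defensive = 1, total = 4))
  expect_equal(irritability_delta(b, b),
               list(aggressive = 0, defensive = 0, total = 0))
  w2 <- irritability_scores(6, 3, rat_id = "B", timepoint = "withdrawal")
  expect_error(irritability_delta(b, w2), class = "addix_data_error")
})

test_that("shock suppression reports difference and ratio with a 0/0 guard", {
  expect_equal(shock_suppression(20, 10), list(difference = 10, ratio = 0.5))
  expect_equal(shock_suppression(15, 15), list(difference = 0, ratio = 1.0))
  res <- shock_suppression(0, 0)
  expect_equal(res$difference, 0)
  expect_true(is.na(res$ratio))
})

test_that("behavior summaries compose the per-rat metrics from session tables", {
  tabs <- tiny_tables()
  s <- behavior_summaries(tabs)
  expect_equal(nrow(s), 3)
  a <- s[s$rat_id == "A", ]
  expect_equal(a$esc_mean_last3, mean(40 + 12:14))
  expect_equal(a$pr_rewards_post_lga, 12L)      # PR session 2 by default
  expect_equal(a$pr_breakpoint, pr_requirement(12))
  expect_equal(a$preshock_infusions, 10L)
  expect_equal(a$shock_infusions, 5L)
  expect_equal(a$irritability_delta_total, (9 + 6) - (6 + 4))
  # switching the motivation source to the post-shock PR session
  s3 <- behavior_summaries(tabs, pr_session = 3)
  expect_equal(s3$pr_rewards_post_lga[s3$rat_id == "A"], 11L)
  # naive rats carry irritability only
  n1 <- s[s$rat_id == "N1", ]
  expect_true(is.na(n1$esc_mean_last3))
  expect_equal(n1$irritability_delta_total, 0.5)
})
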