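# shared fixture builders: everything generated in code, no stored data

# a minimal valid 3-rat study (2 cocaine + 1 naive) with hand-written rows
tiny_tables <- function() {
  rats <- tibble::tibble(
    rat_id = c("A", "B", "N1"),
    sex = c("F", "M", "F"),
    cohort = c(1L, 1L, 1L),
    group = c("cocaine", "cocaine", "naive"),
    excluded = FALSE
  )
  one_rat_sessions <- function(id, lga_base) {
    dplyr::bind_rows(
      tibble::tibble(rat_id = id, phase = "ShA", day_index = 1:10,
                     duration_h = 2, infusions = 15L),
      tibble::tibble(rat_id = id, phase = "LgA", day_index = 1:14,
                     duration_h = 6, infusions = as.integer(lga_base + 1:14)),
      tibble::tibble(rat_id = id, phase = "PR", day_index = 1:3,
                     duration_h = 6, infusions = c(8L, 12L, 11L)),
      tibble::tibble(rat_id = id, phase = c("PreShock", "Shock"),
                     day_index = 1L, duration_h = 1,
                     infusions = c(10L, 5L))
    )
  }
  sessions <- dplyr::bind_rows(
    one_rat_sessions("A", 40), one_rat_sessions("B", 60)
  ) |>
    dplyr::mutate(
      hour1_infusions = as.integer(pmin(infusions, ceiling(infusions / 2))),
      active_presses = infusions + 2L,
      inactive_presses = 1L,
      missing = FALSE
    )
  irritability <- tibble::tibble(
    rat_id = rep(c("A", "B", "N1"), each = 2),
    timepoint = rep(c("baseline", "withdrawal"), 3),
    aggressive = c(6, 9, 5, 8, 6, 6.5),
    defensive = c(4, 6, 5, 6, 4, 4)
  ) |>
    dplyr::mutate(total = aggressive + defensive)
  list(rats = rats, sessions = sessions, irritability = irritability)
}

write_tiny_csvs <- function(dir = withr::local_tempdir(.local_envir = parent.frame())) {
  write_study_tables(tiny_tables(), dir)
  list(rats = file.path(dir, "rats.csv"),
       sessions = file.path(dir, "sessions.csv"),
       irritability = file.path(dir, "irritability.csv"))
}

# brute-force oracle for the 60-min breakpoint rule: try every prefix of the
# reward list and take the longest one consistent with a literal reading of
# "no 60-min period without a completed ratio before termination"
oracle_breakpoint <- function(times, session_minutes = 360, gap = 60) {
  best <- 0L
  for (k in seq_along(times)) {
    pts <- c(0, times[seq_len(k)])
    if (all(diff(pts) < gap)) best <- max(best, k)
  }
  list(n_rewards = best,
       breakpoint = if (best == 0) 0L else pr_requirement(best))
}

# printed progressive-ratio schedule, frozen as the authoritative oracle
printed_pr_schedule <- c(1L, 2L, 4L, 6L, 9L, 12L, 15L, 20L, 25L, 32L,
                         40L, 50L, 62L, 77L, 95L, 118L, 145L, 178L)

default_cohort <- local({
  cache <- new.env(parent = emptyenv())
  function(seed = 101) {
    key <- paste0("s", seed)
    if (is.null(cache[[key]])) {
      cache[[key]] <- simulate_cohort(generator_config(), seed = seed)
    }
    cache[[key]]
  }
})
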