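#' Progressive-ratio response requirement
#'
#' Under the progressive-ratio schedule the cost of the j-th reward follows
#' the exponential progression 1, 2, 4, 6, 9, 12, 15, 20, 25, 32, 40, 50,
#' 62, 77, 95, 118, 145, 178, ... The closed form is
#' `round(5 * exp(0.2 * j)) - 5` with half-away-from-zero rounding; it
#' reproduces the printed schedule exactly over j = 1..18 and extends it
#' beyond.
#'
#' @param j reward index (vectorized), integer >= 1.
#' @return integer response requirement(s).
#' @examples
#' pr_requirement(1:10)
#' @export
pr_requirement <- function(j) {
  if (length(j) == 0) return(integer())
  if (any(is.na(j)) || any(j < 1) || any(j != floor(j))) {
    abort_addix("pr_requirement: j must be integers >= 1", "addix_domain_error")
  }
  as.integer(round_half_up(5 * exp(0.2 * j)) - 5)
}

#' Construct a progressive-ratio session log
#'
#' @param reward_times numeric minutes from session start, strictly
#'   increasing, all within `[0, session_minutes]`.
#' @param session_minutes scheduled session length (default 360).
#' @return object of class `pr_session_log`.
#' @export
pr_session_log <- function(reward_times, session_minutes = 360) {
  reward_times <- as.numeric(reward_times)
  if (any(is.na(reward_times)) || is.unsorted(reward_times, strictly = TRUE)) {
    abort_addix("reward_times must be strictly increasing", "addix_data_error")
  }
  if (length(reward_times) && (min(reward_times) < 0 ||
                               max(reward_times) > session_minutes)) {
    abort_addix("reward_times outside [0, session_minutes]", "addix_data_error")
  }
  structure(
    list(reward_times = reward_times, session_minutes = session_minutes,
         n_rewards = length(reward_times)),
    class = "pr_session_log"
  )
}

#' Breakpoint under the 60-minute termination rule
#'
#' The session terminates at the first period of 60 min or more without a
#' completed ratio. That period may fall between session start and the
#' first completion, between two consecutive completions, or between the
#' last completion and session end (the trailing case ends the session but
#' does not remove any completed reward). The breakpoint is the requirement
#' of the last ratio completed before termination, or 0 when no reward was
#' earned.
#'
#' @param log a [pr_session_log()] (or a numeric vector of reward times,
#'   coerced with the default 360-min session).
#' @param gap_minutes termination threshold, default 60.
#' @return list with `n_rewards` (completions counted) and `breakpoint`
#'   (response requirement of the last counted completion).
#' @examples
#' compute_breakpoint(pr_session_log(c(2, 9, 20, 45)))  # 4 rewards, breakpoint 6
#' @export
compute_breakpoint <- function(log, gap_minutes = 60) {
  if (!inherits(log, "pr_session_log")) log <- pr_session_log(log)
  times <- log$reward_times
  n <- 0L
  prev <- 0
  for (t in times) {
    if (t - prev >= gap_minutes) break
    n <- n + 1L
    prev <- t
  }
  bp <- if (n == 0L) 0L else pr_requirement(n)
  list(n_rewards = n, breakpoint = bp)
}

#' Read a progressive-ratio event log CSV
#'
#' Two-column CSV `reward_index,minutes`, one row per completed ratio.
#'
#' @param path CSV path.
#' @param session_minutes session length (default 360).
#' @return a [pr_session_log()].
#' @export
read_pr_event_log <- function(path, session_minutes = 360) {
  tab <- readr::read_csv(path, col_types = readr::cols(
    reward_index = readr::col_integer(), minutes = readr::col_double()
  ), progress = FALSE)
  tab <- tab[order(tab$reward_index), ]
  pr_session_log(tab$minutes, session_minutes = session_minutes)
}

#' Escalation summary: mean intake over the last three extended-access days
#'
#' @param lga_daily_totals numeric vector of daily long-access infusion
#'   totals (day 1..14 after imputation); `NA` marks unresolved gaps.
#' @param n_days expected number of long-access sessions (default 14).
#' @return mean of the last three days, or `NA` if any of them is missing.
#' @export
escalation_summary <- function(lga_daily_totals, n_days = 14) {
  if (length(lga_daily_totals) != n_days) return(NA_real_)
  last3 <- tail(lga_daily_totals, 3)
  if (any(is.na(last3))) return(NA_real_)
  mean(last3)
}

#' Hourly infusion rate
#'
#' @param infusions count of infusions earned in the session.
#' @param duration_h session duration in hours (> 0).
#' @return infusions per hour.
#' @examples
#' hourly_rate(50, 6)  # ~8.33, i.e. ~8 infusions/hr
#' @export
hourly_rate <- function(infusions, duration_h) {
  if (any(duration_h <= 0)) {
    abort_addix("duration_h must be > 0", "addix_domain_error")
  }
  infusions / duration_h
}

#' Observer-averaged irritability scores for one assay
#'
#' Each trained observer reports summed aggressive and summed defensive
#' responses over the ten bottle-brush trials; the assay score is the mean
#' over observers, and the total is aggressive + defensive.
#'
#' @param aggressive,defensive per-observer non-negative totals (equal
#'   length, >= 1 observer).
#' @param rat_id,timepoint identifiers copied into the record.
#' @return one-row tibble with `rat_id`, `timepoint`, `aggressive`,
#'   `defensive`, `total`.
#' @export
irritability_scores <- function(aggressive, defensive, rat_id = NA_character_,
                                timepoint = NA_character_) {
  if (length(aggressive) < 1 || length(aggressive) != length(defensive)) {
    abort_addix("need >= 1 observer with paired aggressive/defensive totals",
                "addix_data_error")
  }
  if (any(aggressive < 0) || any(defensive < 0)) {
    abort_addix("irritability scores must be non-negative", "addix_data_error")
  }
  agg <- mean(aggressive)
  def <- mean(defensive)
  tibble::tibble(rat_id = rat_id, timepoint = timepoint,
                 aggressive = agg, defensive = def, total = agg + def)
}

#' Withdrawal-minus-baseline irritability change
#'
#' @param baseline,withdrawal one-row irritability records for the same rat.
#' @return list with `aggressive`, `defensive`, `total` differences
#'   (withdrawal - baseline).
#' @export
irritability_delta <- function(baseline, withdrawal) {
  if (!identical(baseline$rat_id, withdrawal$rat_id)) {
    abort_addix("baseline and withdrawal records belong to different rats",
                "addix_data_error")
  }
  list(
    aggressive = withdrawal$aggressive - baseline$aggressive,
    defensive = withdrawal$defensive - baseline$defensive,
    total = withdrawal$total - baseline$total
  )
}

#' Suppression of responding by contingent footshock
#'
#' @param preshock_infusions,shock_infusions non-negative 1-h session counts.
#' @return list with `difference` (preshock - shock) and `ratio`
#'   (shock/preshock, `NA` when preshock is 0).
#' @export
shock_suppression <- function(preshock_infusions, shock_infusions) {
  if (any(preshock_infusions < 0) || any(shock_infusions < 0)) {
    abort_addix("infusion counts must be non-negative", "addix_domain_error")
  }
  list(
    difference = preshock_infusions - shock_infusions,
    ratio = ifelse(preshock_infusions > 0,
                   shock_infusions / preshock_infusions, NA_real_)
  )
}

#' Per-rat behavioral summaries
#'
#' Reduces the session and irritability tables to one row per rat:
#' escalation (mean intake over the last three long-access days, after
#' single-gap imputation), motivation (infusions in the chosen
#' progressive-ratio session after long access, with the breakpoint implied
#' by that reward count), compulsivity (pre-shock and shock 1-h infusion
#' counts), and the baseline-subtracted irritability change. Excluded rats
#' are dropped; naive rats contribute irritability rows only.
#'
#' @param tables list with validated `rats`, `sessions`, `irritability`
#'   (see [read_study_tables()]).
#' @param pr_session which progressive-ratio session indexes motivation:
#'   2 (first post-LgA, the default) or 3 (post-shock).
#' @return tibble, one row per non-excluded rat: `rat_id`, `sex`, `cohort`,
#'   `group`, `esc_mean_last3`, `esc_hourly_rate`, `pr_rewards_post_lga`,
#'   `pr_breakpoint`, `preshock_infusions`, `shock_infusions`,
#'   `shock_suppression_ratio`, `irritability_delta_total`,
#'   `irritability_delta_aggressive`, `irritability_delta_defensive`.
#' @export
behavior_summaries <- function(tables, pr_session = 2) {
  stopifnot(pr_session %in% c(1, 2, 3))
  rats <- dplyr::filter(tables$rats, !.data$excluded)
  sess <- dplyr::filter(tables$sessions, .data$rat_id %in% rats$rat_id)
  irr <- dplyr::filter(tables$irritability, .data$rat_id %in% rats$rat_id)

  esc <- sess |>
    dplyr::filter(.data$phase == "LgA") |>
    dplyr::arrange(.data$rat_id, .data$day_index) |>
    dplyr::group_by(.data$rat_id) |>
    dplyr::summarise(esc_mean_last3 = {
      vals <- rep(NA_real_, 14)
      vals[.data$day_index] <- ifelse(.data$missing, NA_real_,
                                      as.numeric(.data$infusions))
      filled <- withCallingHandlers(
        impute_missing_sessions(vals),
        addix_imputation_warning = function(w) invokeRestart("muffleWarning")
      )
      escalation_summary(filled$values)
    }, .groups = "drop")

  pr <- sess |>
    dplyr::filter(.data$phase == "PR", .data$day_index == pr_session,
                  !.data$missing) |>
    dplyr::group_by(.data$rat_id) |>
    dplyr::summarise(pr_rewards_post_lga = as.integer(.data$infusions[1]),
                     .groups = "drop") |>
    dplyr::mutate(pr_breakpoint = ifelse(
      .data$pr_rewards_post_lga > 0,
      pr_requirement(pmax(.data$pr_rewards_post_lga, 1)), 0L
    ))

  one_phase <- function(ph, col) {
    out <- sess |>
      dplyr::filter(.data$phase == ph, !.data$missing) |>
      dplyr::group_by(.data$rat_id) |>
      dplyr::summarise(val = as.integer(.data$infusions[1]), .groups = "drop")
    names(out)[2] <- col
    out
  }

  irr_delta <- irr |>
    tidyr::pivot_wider(id_cols = "rat_id", names_from = "timepoint",
                       values_from = c("aggressive", "defensive", "total")) |>
    dplyr::mutate(
      irritability_delta_total = .data$total_withdrawal - .data$total_baseline,
      irritability_delta_aggressive =
        .data$aggressive_withdrawal - .data$aggressive_baseline,
      irritability_delta_defensive =
        .data$defensive_withdrawal - .data$defensive_baseline
    ) |>
    dplyr::select("rat_id", dplyr::starts_with("irritability_delta"))

  out <- rats |>
    dplyr::select("rat_id", "sex", "cohort", "group") |>
    dplyr::left_join(esc, by = "rat_id") |>
    dplyr::left_join(pr, by = "rat_id") |>
    dplyr::left_join(one_phase("PreShock", "preshock_infusions"), by = "rat_id") |>
    dplyr::left_join(one_phase("Shock", "shock_infusions"), by = "rat_id") |>
    dplyr::left_join(irr_delta, by = "rat_id")
  out$esc_hourly_rate <- out$esc_mean_last3 / 6
  out$shock_suppression_ratio <- ifelse(
    !is.na(out$preshock_infusions) & out$preshock_infusions > 0,
    out$shock_infusions / out$preshock_infusions, NA_real_
  )
  dplyr::relocate(out, "esc_hourly_rate", .after = "esc_mean_last3")
}
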