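#' Cohort-by-sex Z-scores
#'
#' Standardizes a raw behavioral measure within each (cohort, sex) group:
#' `z = (x - mu) / sigma` with the group mean and sample (n-1) standard
#' deviation. Grouping absorbs cohort and sex effects so animals are ranked
#' against their own testing group. Missing inputs stay missing; every
#' group must have at least two non-missing values and positive SD.
#'
#' @param values numeric raw measure, one per rat (`NA` allowed).
#' @param cohort,sex grouping keys, same length as `values`.
#' @return list with `z` (numeric, same order) and `spec` (tibble of group
#'   `cohort`, `sex`, `n`, `mu`, `sigma`).
#' @examples
#' group_zscore(c(1, 2, 3), cohort = c(1, 1, 1), sex = c("F", "F", "F"))$z
#' @export
group_zscore <- function(values, cohort, sex) {
  stopifnot(length(cohort) == length(values), length(sex) == length(values))
  key <- paste(cohort, sex, sep = "/")
  ok <- !is.na(values)
  spec <- tibble::tibble(cohort = cohort[ok], sex = sex[ok], x = values[ok]) |>
    dplyr::group_by(.data$cohort, .data$sex) |>
    dplyr::summarise(n = dplyr::n(), mu = mean(.data$x), sigma = sd(.data$x),
                     .groups = "drop")
  bad <- spec$n < 2 | is.na(spec$sigma) | spec$sigma <= 0
  if (any(bad)) {
    abort_addix(sprintf(
      "group(s) with <2 values or zero SD: %s",
      paste(paste(spec$cohort[bad], spec$sex[bad], sep = "/"), collapse = ", ")
    ), "addix_zscore_error")
  }
  skey <- paste(spec$cohort, spec$sex, sep = "/")
  idx <- match(key, skey)
  z <- (values - spec$mu[idx]) / spec$sigma[idx]
  list(z = z, spec = spec)
}

#' Addiction Index of one or more index rows
#'
#' Unweighted mean of the escalation, motivation and compulsivity Z-score
#' indices; irritability is deliberately excluded (it is orthogonal to the
#' shared severity construct). Missing whenever any of the three components
#' is missing (complete-case).
#'
#' @param escalation_z,motivation_z,compulsivity_z numeric (vectorized).
#' @return numeric Addiction Index values.
#' @export
addiction_index <- function(escalation_z, motivation_z, compulsivity_z) {
  (escalation_z + motivation_z + compulsivity_z) / 3
}

#' Resilient/vulnerable classification
#'
#' A rat is resilient when its mean daily intake over the last three
#' long-access (6-h) sessions stays under 50 infusions per session (about
#' 8 infusions/hr, the level typical of short access); 50 or more is
#' vulnerable.
#'
#' @param esc_mean_last3 mean infusions per session over the last three
#'   long-access days (vectorized, `NA` allowed).
#' @param threshold infusions/session cut, default 50.
#' @return character vector `"resilient"`/`"vulnerable"` (`NA` propagated).
#' @export
classify_vulnerability <- function(esc_mean_last3, threshold = 50) {
  if (any(esc_mean_last3 < 0, na.rm = TRUE)) {
    abort_addix("esc_mean_last3 must be non-negative", "addix_domain_error")
  }
  ifelse(is.na(esc_mean_last3), NA_character_,
         ifelse(esc_mean_last3 < threshold, "resilient", "vulnerable"))
}

#' Severity quartile groups of the Addiction Index
#'
#' Ranks rats by Addiction Index (ascending; ties broken by input order)
#' and cuts the ranking at cumulative counts `round_half_up(N * k/4)` for
#' k = 1..3, labeling the four blocks Low, Mild, Moderate, Severe. This cut
#' convention makes group sizes differ by at most one (e.g. 128/128/127/128
#' at N = 511). Rats with missing AI are left unassigned (`NA`).
#'
#' @param ai_values numeric Addiction Index, one per rat.
#' @return factor with levels Low, Mild, Moderate, Severe (and `NA` for
#'   missing AI), in input order.
#' @export
severity_groups <- function(ai_values) {
  lv <- c("Low", "Mild", "Moderate", "Severe")
  ok <- which(!is.na(ai_values))
  n_ok <- length(ok)
  if (n_ok < 4) {
    abort_addix("need at least 4 rats with non-missing Addiction Index",
                "addix_domain_error")
  }
  cuts <- round_half_up(n_ok * (1:3) / 4)
  ranks <- rank(ai_values[ok], ties.method = "first")
  lab <- lv[findInterval(ranks, c(cuts + 0.5), left.open = FALSE) + 1]
  out <- rep(NA_character_, length(ai_values))
  out[ok] <- lab
  factor(out, levels = lv)
}

#' Build the per-rat index table
#'
#' Converts behavioral summaries into the four cohort-by-sex Z-score
#' indices (escalation: mean intake over the last three long-access days;
#' motivation: infusions in the post-LgA progressive-ratio session;
#' compulsivity: infusions despite contingent footshock; irritability:
#' baseline-subtracted total irritability), the Addiction Index (mean of
#' the first three), the resilient/vulnerable label, and the severity
#' quartile. Only non-excluded cocaine rats enter; per-index missing values
#' propagate, and the Addiction Index is complete-case.
#'
#' @param summaries output of [behavior_summaries()].
#' @return tibble: `rat_id`, `sex`, `cohort`, `escalation_z`,
#'   `motivation_z`, `compulsivity_z`, `irritability_z`, `addiction_index`,
#'   `vulnerability`, `severity`.
#' @export
build_indices <- function(summaries) {
  s <- dplyr::filter(summaries, .data$group == "cocaine")
  zs <- function(col) group_zscore(s[[col]], s$cohort, s$sex)$z
  out <- tibble::tibble(
    rat_id = s$rat_id, sex = s$sex, cohort = s$cohort,
    escalation_z = zs("esc_mean_last3"),
    motivation_z = zs("pr_rewards_post_lga"),
    compulsivity_z = zs("shock_infusions"),
    irritability_z = zs("irritability_delta_total")
  )
  out$addiction_index <- addiction_index(out$escalation_z, out$motivation_z,
                                         out$compulsivity_z)
  out$vulnerability <- classify_vulnerability(s$esc_mean_last3)
  out$severity <- severity_groups(out$addiction_index)
  out
}
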