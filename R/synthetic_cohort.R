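#' Synthetic-cohort generator configuration
#'
#' Defaults encode the population structure the pipeline assumes: a
#' resilient/vulnerable mixture (about 20/80), a single latent severity
#' factor inducing pairwise correlation `lambda^2` (default 0.46) among the
#' escalation, motivation and compulsivity latents with irritability
#' orthogonal, standardized sex effects, shock suppression calibrated so
#' pre-shock responding predicts shock responding at r of about 0.58, and
#' elevated withdrawal irritability in cocaine versus naive animals
#' (d = 0.89).
#'
#' @param n_rats number of cocaine self-administering rats.
#' @param p_female proportion female; realized exactly as
#'   `round(p_female * n)` females in a random order.
#' @param p_vulnerable per-rat Bernoulli probability of the vulnerable
#'   (escalating) trajectory class.
#' @param n_cohorts experimental cohorts; rats are assigned balanced.
#' @param lambda loading of each addiction latent on the shared severity
#'   factor; pairwise latent correlation is `lambda^2`.
#' @param sex_effect_d named standardized female-minus-male shifts for
#'   `escalation`, `motivation`, `compulsivity`, `irritability`.
#' @param resilient_mean,resilient_sd flat long-access daily intake for the
#'   resilient class (infusions/day).
#' @param vulnerable_start,vulnerable_final vulnerable long-access intake at
#'   day 1 and the day-14 ramp target (infusions/day).
#' @param lga_noise_sd day-to-day intake noise (infusions).
#' @param sha_mean,sha_sd short-access daily intake.
#' @param suppression_noise_sd SD of the session-level noise inside the
#'   logistic suppression term; 1.65 calibrates corr(preshock, shock) to
#'   about 0.58.
#' @param irritability_withdrawal_d standardized withdrawal elevation of
#'   total irritability in cocaine rats versus naive.
#' @param n_naive naive comparison animals (irritability records only).
#' @return list of class `generator_config`.
#' @export
generator_config <- function(n_rats = 567,
                             p_female = 0.5,
                             p_vulnerable = 0.80,
                             n_cohorts = 12,
                             lambda = 0.678,
                             sex_effect_d = c(escalation = 0.41,
                                              motivation = 0.32,
                                              compulsivity = 0.67,
                                              irritability = 0),
                             resilient_mean = 35, resilient_sd = 6,
                             vulnerable_start = 55, vulnerable_final = 95,
                             lga_noise_sd = 8,
                             sha_mean = 16, sha_sd = 4,
                             suppression_noise_sd = 1.65,
                             irritability_withdrawal_d = 0.89,
                             n_naive = 49) {
  cfg <- list(
    n_rats = n_rats, p_female = p_female, p_vulnerable = p_vulnerable,
    n_cohorts = n_cohorts, lambda = lambda,
    sex_effect_d = sex_effect_d,
    resilient_mean = resilient_mean, resilient_sd = resilient_sd,
    vulnerable_start = vulnerable_start, vulnerable_final = vulnerable_final,
    lga_noise_sd = lga_noise_sd, sha_mean = sha_mean, sha_sd = sha_sd,
    suppression_noise_sd = suppression_noise_sd,
    irritability_withdrawal_d = irritability_withdrawal_d,
    n_naive = n_naive
  )
  validate_generator_config(cfg)
  structure(cfg, class = "generator_config")
}

validate_generator_config <- function(cfg) {
  probs <- c(cfg$p_female, cfg$p_vulnerable)
  if (any(probs < 0 | probs > 1)) {
    abort_addix("probabilities must lie in [0, 1]", "addix_config_error")
  }
  if (cfg$n_rats < 0 || cfg$n_naive < 0) {
    abort_addix("n_rats and n_naive must be >= 0", "addix_config_error")
  }
  if (cfg$lambda < 0 || cfg$lambda^2 >= 1) {
    abort_addix("lambda must satisfy 0 <= lambda^2 < 1", "addix_config_error")
  }
  need <- c("escalation", "motivation", "compulsivity", "irritability")
  if (!all(need %in% names(cfg$sex_effect_d))) {
    abort_addix("sex_effect_d must name escalation, motivation, compulsivity, irritability",
                "addix_config_error")
  }
  invisible(cfg)
}

#' Load a generator configuration from YAML or JSON
#'
#' Fields mirror [generator_config()] arguments; unspecified fields keep
#' their defaults.
#'
#' @param path YAML (`.yml`/`.yaml`) or JSON file.
#' @return a `generator_config`.
#' @export
read_generator_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (!is.null(raw$sex_effect_d)) raw$sex_effect_d <- unlist(raw$sex_effect_d)
  do.call(generator_config, raw[names(raw) %in% names(formals(generator_config))])
}

#' Simulate a study cohort with latent ground truth
#'
#' Generative model (one draw per rat, deterministic given `(config, seed)`):
#' severity `a ~ N(0,1)`; addiction latents
#' `b_k = lambda * a + sqrt(1 - lambda^2) * e_k` for escalation, motivation
#' and compulsivity, an independent `N(0,1)` irritability latent, and
#' additive standardized sex shifts of `+d_k/2` (females) or `-d_k/2`
#' (males). Short-access intake is flat Gaussian with a small female
#' acquisition ramp; long-access intake is flat for resilient rats and a
#' linear ramp scaled by `(1 + 0.3 * b_esc)` for vulnerable rats.
#' Progressive-ratio rewards are `round(12 + 6 * b_mot)` plus a +5 boost
#' after long access. Pre-shock 1-h infusions are `round(10 + 3a)`; shock
#' infusions apply a logistic suppression factor
#' `plogis(0.8 * b_comp - 0.4 + noise)` with the compulsivity sex shift
#' added on the count scale (scaled by the cohort SD of unshifted counts)
#' so the configured Cohen's d is realized on the observed measure.
#' Irritability totals are baseline `N(15, 4)` with withdrawal elevation
#' `0.89 * 4` for cocaine rats plus `4 * b_irr`; aggressive/defensive split
#' 60/40. All counts are rounded and floored at zero.
#'
#' @param config a [generator_config()].
#' @param seed integer RNG seed; identical `(config, seed)` give identical
#'   output.
#' @return list with tibbles `rats`, `sessions`, `irritability` (valid per
#'   the data-model schemas) and `truth` (per-rat latents: `severity`,
#'   `class`, and the true standardized index values `b_escalation`,
#'   `b_motivation`, `b_compulsivity`, `b_irritability`).
#' @examples
#' cohort <- simulate_cohort(generator_config(n_rats = 20, n_cohorts = 2), seed = 1)
#' table(cohort$truth$class)
#' @export
simulate_cohort <- function(config = generator_config(), seed) {
  validate_generator_config(config)
  withr::with_seed(as.integer(seed), simulate_cohort_impl(config))
}

simulate_cohort_impl <- function(cfg) {
  n <- cfg$n_rats
  n_all <- n + cfg$n_naive
  ids <- sprintf("RAT%05d", seq_len(max(n_all, 0)))
  coc_ids <- head(ids, n)
  naive_ids <- if (cfg$n_naive > 0) tail(ids, cfg$n_naive) else character()

  sex_of <- function(m, p) {
    if (m == 0) return(character())
    nf <- round_half_up(p * m)
    sample(rep(c("F", "M"), c(nf, m - nf)))
  }
  sex <- sex_of(n, cfg$p_female)
  sex_naive <- sex_of(cfg$n_naive, cfg$p_female)
  cohort <- if (n > 0) sample(rep_len(seq_len(cfg$n_cohorts), n)) else integer()
  cohort_naive <- if (cfg$n_naive > 0) {
    sample(rep_len(seq_len(cfg$n_cohorts), cfg$n_naive))
  } else integer()

  cls <- if (n > 0) {
    ifelse(rbinom(n, 1, cfg$p_vulnerable) == 1, "vulnerable", "resilient")
  } else character()
  a <- rnorm(n)
  lam <- cfg$lambda
  res <- sqrt(1 - lam^2)
  d <- cfg$sex_effect_d
  shift <- function(dk) ifelse(sex == "F", dk / 2, -dk / 2)
  b_esc <- lam * a + res * rnorm(n) + shift(d[["escalation"]])
  b_mot <- lam * a + res * rnorm(n) + shift(d[["motivation"]])
  # compulsivity sex effect is applied on the count scale below, so the
  # configured d survives the nonlinear suppression map
  b_comp <- lam * a + res * rnorm(n)
  b_irr <- rnorm(n) + shift(d[["irritability"]])
  b_irr_naive <- rnorm(cfg$n_naive)

  count <- function(x) as.integer(pmax(0, round(x)))

  # short access: 10 x 2-h days, females ramp up to +4 infusions by day 10
  sha <- lapply(seq_len(n), function(i) {
    ramp <- if (sex[i] == "F") 4 * (0:9) / 9 else rep(0, 10)
    count(rnorm(10, cfg$sha_mean, cfg$sha_sd) + ramp)
  })

  # long access: 14 x 6-h days
  frac <- (0:13) / 13
  lga <- lapply(seq_len(n), function(i) {
    mu <- if (cls[i] == "resilient") {
      rnorm(14, cfg$resilient_mean, cfg$resilient_sd)
    } else {
      cfg$vulnerable_start +
        frac * (cfg$vulnerable_final - cfg$vulnerable_start) * (1 + 0.3 * b_esc[i]) +
        rnorm(14, 0, cfg$lga_noise_sd)
    }
    count(mu)
  })

  # progressive ratio: PR1 after ShA, PR2/PR3 after LgA (+5 boost)
  pr <- vapply(seq_len(n), function(i) {
    count(12 + 6 * b_mot[i] + c(0, 5, 5))
  }, integer(3))
  pr <- if (n > 0) t(pr) else matrix(integer(), 0, 3)

  # pre-shock and shock 1-h sessions; suppression is logistic in the
  # compulsivity latent with session noise calibrated for r ~ 0.58
  preshock <- count(10 + 3 * a)
  s_fac <- plogis(0.8 * b_comp - 0.4 + rnorm(n, 0, cfg$suppression_noise_sd))
  shock_raw <- preshock * s_fac
  comp_shift <- if (n > 1 && sd(shock_raw) > 0) {
    ifelse(sex == "F", 1, -1) * d[["compulsivity"]] / 2 * sd(shock_raw)
  } else 0
  shock <- count(shock_raw + comp_shift)

  # bottle-brush irritability: baseline and withdrawal totals, 60/40 split
  irr_rows <- function(id_v, sex_v, b_v, cocaine) {
    m <- length(id_v)
    if (m == 0) return(empty_irritability())
    base <- pmax(0, rnorm(m, 15, 4))
    delta <- cfg$irritability_withdrawal_d * 4 * as.numeric(cocaine)
    wd <- pmax(0, base + delta + 4 * b_v)
    tibble::tibble(
      rat_id = rep(id_v, 2),
      timepoint = rep(c("baseline", "withdrawal"), each = m),
      total = c(base, wd)
    ) |>
      dplyr::mutate(aggressive = 0.6 * .data$total,
                    defensive = 0.4 * .data$total) |>
      dplyr::select("rat_id", "timepoint", "aggressive", "defensive", "total")
  }
  irritability <- dplyr::bind_rows(
    irr_rows(coc_ids, sex, b_irr, TRUE),
    irr_rows(naive_ids, sex_naive, b_irr_naive, FALSE)
  )

  session_block <- function(ph, counts_by_rat) {
    n_days <- .phase_days[[ph]]
    inf <- unlist(counts_by_rat, use.names = FALSE)
    if (is.null(inf)) inf <- integer()
    m <- length(inf)
    h1 <- as.integer(pmin(inf, round(inf * switch(ph, ShA = 0.55, LgA = 0.35, 1))))
    tibble::tibble(
      rat_id = rep(coc_ids, each = n_days),
      phase = ph,
      day_index = rep.int(seq_len(n_days), n),
      duration_h = .phase_duration[[ph]],
      infusions = inf,
      hour1_infusions = h1,
      active_presses = inf + as.integer(round(0.2 * inf)),
      inactive_presses = rep.int(2L, m),
      missing = FALSE
    )
  }

  sessions <- if (n == 0) empty_sessions() else dplyr::bind_rows(
    session_block("ShA", sha),
    session_block("LgA", lga),
    session_block("PR", lapply(seq_len(n), function(i) pr[i, ])),
    session_block("PreShock", as.list(preshock)),
    session_block("Shock", as.list(shock))
  )

  rats <- tibble::tibble(
    rat_id = c(coc_ids, naive_ids),
    sex = c(sex, sex_naive),
    cohort = as.integer(c(cohort, cohort_naive)),
    group = rep(c("cocaine", "naive"), c(n, cfg$n_naive)),
    excluded = FALSE
  )

  truth <- tibble::tibble(
    rat_id = coc_ids,
    sex = sex,
    cohort = as.integer(cohort),
    class = cls,
    severity = a,
    b_escalation = b_esc,
    b_motivation = b_mot,
    b_compulsivity = b_comp,
    b_irritability = b_irr
  )

  validate_rats(rats)
  validate_sessions(sessions, rats)
  validate_irritability(irritability, rats)
  list(rats = rats, sessions = sessions, irritability = irritability,
       truth = truth)
}

#' Evenly spaced progressive-ratio reward log
#'
#' Fixture builder for breakpoint testing: `n_rewards` completions at a
#' constant inter-reward interval, starting one interval into the session.
#'
#' @param n_rewards number of completed ratios (>= 0).
#' @param inter_reward_minutes spacing between completions.
#' @param session_minutes session length (default 360).
#' @return a [pr_session_log()].
#' @examples
#' compute_breakpoint(generate_pr_event_log(4, 10))  # 4 rewards, breakpoint 6
#' @export
generate_pr_event_log <- function(n_rewards, inter_reward_minutes,
                                  session_minutes = 360) {
  if (n_rewards < 0) abort_addix("n_rewards must be >= 0", "addix_config_error")
  times <- seq_len(n_rewards) * inter_reward_minutes
  if (n_rewards > 0 && max(times) > session_minutes) {
    abort_addix("events exceed session length", "addix_config_error")
  }
  pr_session_log(times, session_minutes = session_minutes)
}
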