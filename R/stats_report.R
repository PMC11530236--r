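#' Cohen's d with 95% confidence interval
#'
#' Standardized mean difference `d = (mean(x) - mean(y)) / s_pooled` with
#' the pooled (n-1) SD. The default interval is the asymptotic normal one,
#' `d +/- 1.96 * se` with
#' `se = sqrt((n1 + n2)/(n1 * n2) + d^2 / (2 * (n1 + n2 - 2)))`, chosen for
#' determinism and transparency; `ci = "nct"` inverts the noncentral-t
#' distribution instead.
#'
#' @param x,y numeric samples (n >= 2 each).
#' @param ci `"asymptotic"` (default) or `"nct"`.
#' @param conf confidence level, default 0.95.
#' @return tibble row: `statistic`, `estimate`, `ci_low`, `ci_high`, `n1`,
#'   `n2`, `p_value` (two-sided, from the pooled t-test).
#' @examples
#' cohens_d(c(2, 3, 4), c(0, 1, 2))
#' @export
cohens_d <- function(x, y, ci = c("asymptotic", "nct"), conf = 0.95) {
  ci <- match.arg(ci)
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2 || n2 < 2) abort_addix("need n >= 2 per group", "addix_stat_error")
  sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2)
  if (sp2 <= 0) abort_addix("pooled SD is zero", "addix_stat_error")
  d <- (mean(x) - mean(y)) / sqrt(sp2)
  se <- sqrt((n1 + n2) / (n1 * n2) + d^2 / (2 * (n1 + n2 - 2)))
  if (ci == "asymptotic") {
    zc <- qnorm(1 - (1 - conf) / 2)
    lo <- d - zc * se
    hi <- d + zc * se
  } else {
    # invert the noncentral-t CDF of the observed t for the ncp bounds
    tobs <- d * sqrt(n1 * n2 / (n1 + n2))
    df <- n1 + n2 - 2
    alpha <- (1 - conf) / 2
    # pt() with ncp emits benign "full precision" notices near the tails
    f <- function(ncp, p) suppressWarnings(pt(tobs, df, ncp = ncp)) - p
    span <- abs(tobs) + 10
    lo_ncp <- tryCatch(
      stats::uniroot(f, c(-span, span), p = 1 - alpha, extendInt = "yes")$root,
      error = function(e) NA_real_)
    hi_ncp <- tryCatch(
      stats::uniroot(f, c(-span, span), p = alpha, extendInt = "yes")$root,
      error = function(e) NA_real_)
    sc <- sqrt((n1 + n2) / (n1 * n2))
    lo <- lo_ncp * sc
    hi <- hi_ncp * sc
  }
  tt <- t.test(x, y, var.equal = TRUE)
  tibble::tibble(statistic = "cohens_d", estimate = d, ci_low = lo,
                 ci_high = hi, n1 = n1, n2 = n2,
                 p_value = unname(tt$p.value))
}

#' Pearson correlation with two-sided p value
#'
#' @param x,y paired numeric samples (n >= 3 after pairwise NA removal).
#' @return tibble row as in [cohens_d()] (`ci` from the Fisher transform).
#' @export
pearson_r <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) abort_addix("need n >= 3 pairs", "addix_stat_error")
  if (sd(x) == 0 || sd(y) == 0) {
    abort_addix("constant input has no defined correlation", "addix_stat_error")
  }
  ct <- cor.test(x, y, method = "pearson")
  tibble::tibble(statistic = "pearson_r", estimate = unname(ct$estimate),
                 ci_low = ct$conf.int[1], ci_high = ct$conf.int[2],
                 n1 = length(x), n2 = length(y),
                 p_value = unname(ct$p.value))
}

#' Two-group Student's t-test
#'
#' Pooled-variance unpaired test, or paired test on the differences.
#'
#' @param x,y numeric samples; equal lengths when `paired`.
#' @param paired logical, default `FALSE`.
#' @return tibble row: `statistic` (`"t"`), `estimate` (mean difference),
#'   `ci_low`/`ci_high` (its CI), `n1`, `n2`, `p_value`, plus the `t`
#'   statistic and `df`.
#' @export
two_group_t <- function(x, y, paired = FALSE) {
  if (paired) {
    ok <- !is.na(x) & !is.na(y)
    x <- x[ok]; y <- y[ok]
    if (length(x) < 2) abort_addix("need n >= 2 pairs", "addix_stat_error")
    if (sd(x - y) == 0) {
      abort_addix("zero variance of paired differences", "addix_stat_error")
    }
    tt <- t.test(x, y, paired = TRUE)
  } else {
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    if (length(x) < 2 || length(y) < 2) {
      abort_addix("need n >= 2 per group", "addix_stat_error")
    }
    tt <- t.test(x, y, var.equal = TRUE)
  }
  est <- if (paired) unname(tt$estimate) else {
    unname(tt$estimate[1] - tt$estimate[2])
  }
  tibble::tibble(statistic = "t", estimate = est,
                 ci_low = tt$conf.int[1], ci_high = tt$conf.int[2],
                 n1 = length(x), n2 = length(y),
                 p_value = unname(tt$p.value), t = unname(tt$statistic),
                 df = unname(tt$parameter))
}

#' PCA of the behavioral index matrix
#'
#' Centers and scales each column to unit sample SD and computes principal
#' components (`stats::prcomp`), i.e. the eigenstructure of the correlation
#' matrix. Loading signs are fixed so each component's largest-magnitude
#' loading is positive, making results reproducible across linear-algebra
#' backends.
#'
#' @param x numeric matrix or data frame, rats in rows, index variables in
#'   columns; rows with any `NA` are dropped (complete-case).
#' @return list of class `addix_pca`: `loadings` (variables x components),
#'   `explained_fraction`, `sdev`, `n` (rows used), `scores`.
#' @export
pca_indices <- function(x) {
  x <- as.matrix(x)
  keep <- stats::complete.cases(x)
  x <- x[keep, , drop = FALSE]
  if (nrow(x) < 2 || ncol(x) < 2) {
    abort_addix("need >= 2 complete rows and >= 2 variables", "addix_stat_error")
  }
  if (any(apply(x, 2, sd) == 0)) {
    abort_addix("constant column cannot be scaled", "addix_stat_error")
  }
  pc <- prcomp(x, center = TRUE, scale. = TRUE)
  rot <- pc$rotation
  flip <- apply(rot, 2, function(v) sign(v[which.max(abs(v))]))
  rot <- sweep(rot, 2, flip, `*`)
  scores <- sweep(pc$x, 2, flip, `*`)
  ev <- pc$sdev^2
  structure(list(
    loadings = rot,
    explained_fraction = ev / sum(ev),
    sdev = pc$sdev,
    n = nrow(x),
    scores = scores
  ), class = "addix_pca")
}

#' @export
print.addix_pca <- function(x, ...) {
  cat("PCA of", nrow(x$loadings), "index variables on", x$n, "rats\n")
  cat("explained variance (%):",
      paste(sprintf("%.1f", 100 * x$explained_fraction), collapse = ", "), "\n")
  print(round(x$loadings, 3))
  invisible(x)
}

#' Per-group sample size for a two-sample t-test
#'
#' Smallest integer n per group giving at least the target power for a
#' two-sided two-sample t-test under a noncentral-t alternative with
#' standardized effect `d`, found by incrementing n from 2.
#'
#' @param d standardized effect size (> 0).
#' @param alpha two-sided significance level, default 0.05.
#' @param power target power, default 0.80.
#' @return integer n per group.
#' @examples
#' n_per_group_for_power(0.67)  # 36
#' @export
n_per_group_for_power <- function(d, alpha = 0.05, power = 0.80) {
  if (d <= 0) abort_addix("d must be > 0", "addix_domain_error")
  if (alpha <= 0 || alpha >= 1 || power <= 0 || power >= 1) {
    abort_addix("alpha and power must lie in (0, 1)", "addix_domain_error")
  }
  n <- 2L
  repeat {
    df <- 2 * n - 2
    crit <- qt(1 - alpha / 2, df)
    ncp <- d * sqrt(n / 2)
    pw <- 1 - pt(crit, df, ncp = ncp) + pt(-crit, df, ncp = ncp)
    if (pw >= power) return(n)
    n <- n + 1L
  }
}

#' Standard statistical battery for one cohort
#'
#' Runs the report-stage statistics on the behavioral summaries and index
#' table: sex effect sizes (Cohen's d, F vs M) for each behavioral measure,
#' the cocaine-vs-naive irritability effect, the pre-shock/shock Pearson
#' correlation and paired t-test, and the per-group sample size needed to
#' detect each significant positive sex effect at alpha = 0.05 with 80%
#' power.
#'
#' @param summaries output of [behavior_summaries()].
#' @param indices output of [build_indices()].
#' @param include_irritability_in_pca include the irritability index as a
#'   fourth PCA column (default `TRUE`).
#' @return list with `tests` (tibble of stat rows, one per test) and `pca`
#'   (an `addix_pca` of the index matrix).
#' @export
stats_battery <- function(summaries, indices,
                          include_irritability_in_pca = TRUE) {
  coc <- dplyr::filter(summaries, .data$group == "cocaine")
  f <- coc$sex == "F"
  sex_d <- function(col, name) {
    res <- cohens_d(coc[[col]][f], coc[[col]][!f])
    res$statistic <- paste0("sex_d_", name)
    res
  }
  naive <- dplyr::filter(summaries, .data$group == "naive")
  irr_d <- cohens_d(coc$irritability_delta_total,
                    naive$irritability_delta_total)
  irr_d$statistic <- "withdrawal_irritability_d_vs_naive"

  pre <- coc$preshock_infusions
  sho <- coc$shock_infusions
  r <- pearson_r(pre, sho)
  r$statistic <- "preshock_shock_r"
  tt <- two_group_t(pre, sho, paired = TRUE)
  tt$statistic <- "preshock_shock_paired_t"

  tests <- dplyr::bind_rows(
    sex_d("esc_mean_last3", "escalation"),
    sex_d("pr_rewards_post_lga", "motivation"),
    sex_d("shock_infusions", "compulsivity"),
    sex_d("irritability_delta_total", "irritability"),
    irr_d, r, tt
  )

  sig_sex <- tests[grepl("^sex_d_", tests$statistic) &
                     tests$p_value < 0.05 & tests$estimate > 0, ]
  if (nrow(sig_sex)) {
    power_rows <- tibble::tibble(
      statistic = sub("^sex_d_", "n_per_group_80pct_power_", sig_sex$statistic),
      estimate = vapply(sig_sex$estimate, n_per_group_for_power, numeric(1)),
      ci_low = NA_real_, ci_high = NA_real_,
      n1 = sig_sex$n1, n2 = sig_sex$n2, p_value = NA_real_
    )
    tests <- dplyr::bind_rows(tests, power_rows)
  }

  cols <- c("escalation_z", "motivation_z", "compulsivity_z",
            if (include_irritability_in_pca) "irritability_z")
  pca <- pca_indices(indices[, cols])
  list(tests = tests, pca = pca)
}
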