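test_that("Cohen's d and its asymptotic CI match hand arithmetic", {
  res <- cohens_d(c(2, 3, 4), c(0, 1, 2))
  expect_equal(res$estimate, 2)
  se <- sqrt(6 / 9 + 4 / 8)
  expect_equal(res$ci_low, 2 - 1.959964 * se, tolerance = 1e-5)
  expect_equal(res$ci_high, 2 + 1.959964 * se, tolerance = 1e-5)
  same <- cohens_d(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(same$estimate, 0)
  expect_equal(same$ci_low, -same$ci_high)
  expect_error(cohens_d(c(1, 1), c(1, 1)), class = "addix_stat_error")
})

test_that("Cohen's d recovers a configured shift in large samples", {
  set.seed(31)
  x <- rnorm(5000, 0.67, 1)
  y <- rnorm(5000, 0, 1)
  res <- cohens_d(x, y)
  expect_gt(res$estimate, 0.60)
  expect_lt(res$estimate, 0.74)
  expect_true(res$ci_low <= res$estimate && res$estimate <= res$ci_high)
})

test_that("Cohen's d is antisymmetric and scale invariant", {
  set.seed(32)
  for (i in 1:20) {
    x <- rnorm(sample(5:30, 1), sample(0:3, 1))
    y <- rnorm(sample(5:30, 1))
    expect_equal(cohens_d(x, y)$estimate, -cohens_d(y, x)$estimate)
    a <- runif(1, 0.5, 4); b <- runif(1, -5, 5)
    expect_equal(cohens_d(a * x + b, a * y + b)$estimate,
                 cohens_d(x, y)$estimate, tolerance = 1e-10)
  }
})

test_that("the noncentral-t CI option brackets the asymptotic one sensibly", {
  set.seed(33)
  x <- rnorm(40, 1); y <- rnorm(35)
  asym <- cohens_d(x, y)
  nct <- cohens_d(x, y, ci = "nct")
  expect_equal(nct$estimate, asym$estimate)
  expect_true(nct$ci_low <= nct$estimate && nct$estimate <= nct$ci_high)
  expect_equal(nct$ci_low, asym$ci_low, tolerance = 0.05)
  expect_equal(nct$ci_high, asym$ci_high, tolerance = 0.05)
})

test_that("Pearson r matches closed-form values and affine invariance", {
  x <- c(1, 2, 3)
  expect_equal(pearson_r(x, x)$estimate, 1)
  expect_equal(pearson_r(x, -x)$estimate, -1)
  expect_equal(pearson_r(x, c(2, 2, 4))$estimate, sqrt(3) / 2, tolerance = 1e-10)
  expect_error(pearson_r(x, c(5, 5, 5)), class = "addix_stat_error")
  set.seed(34)
  u <- rnorm(50); v <- rnorm(50)
  expect_equal(pearson_r(2 * u + 3, v)$estimate, pearson_r(u, v)$estimate,
               tolerance = 1e-12)
})

test_that("two-group t matches hand arithmetic and flags degenerate pairs", {
  res <- two_group_t(c(2, 3, 4), c(0, 1, 2))
  expect_equal(res$t, 2.449, tolerance = 1e-3)
  expect_equal(res$df, 4)
  expect_equal(res$estimate, 2)
  ident <- two_group_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(ident$t, 0)
  expect_equal(ident$p_value, 1)
  expect_error(two_group_t(c(2, 3, 4), c(1, 2, 3), paired = TRUE),
               class = "addix_stat_error")  # constant difference
  paired <- two_group_t(c(5, 7, 9, 6), c(1, 2, 3, 5), paired = TRUE)
  expect_equal(paired$estimate, mean(c(4, 5, 6, 1)))
})

test_that("PCA explained fractions and loadings match an eigendecomposition oracle", {
  set.seed(35)
  x <- matrix(rnorm(200 * 4), 200, 4)
  x[, 2] <- x[, 1] * 0.5 + x[, 2]
  got <- pca_indices(x)
  ev <- eigen(cor(x), symmetric = TRUE)
  expect_equal(got$explained_fraction, ev$values / sum(ev$values),
               tolerance = 1e-10)
  for (k in 1:4) {
    expect_equal(abs(got$loadings[, k]), abs(ev$vectors[, k]),
                 tolerance = 1e-8, ignore_attr = TRUE)
    expect_gt(got$loadings[which.max(abs(got$loadings[, k])), k], 0)
  }
  expect_equal(sum(got$explained_fraction), 1, tolerance = 1e-9)
  expect_equal(crossprod(got$loadings), diag(4), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("PCA handles exact collinearity and the independence limit", {
  set.seed(36)
  x <- rnorm(100)
  dup <- pca_indices(cbind(x, x))
  expect_equal(dup$explained_fraction, c(1, 0), tolerance = 1e-9)
  ind <- pca_indices(matrix(rnorm(4 * 20000), ncol = 4))
  expect_equal(ind$explained_fraction, rep(0.25, 4), tolerance = 0.02)
  expect_error(pca_indices(cbind(x, rep(1, 100))), class = "addix_stat_error")
})

test_that("scaled PCA reconstructs the standardized matrix from all components", {
  set.seed(37)
  x <- matrix(rnorm(50 * 3), 50, 3)
  p <- pca_indices(x)
  z <- scale(x)
  recon <- p$scores %*% t(p$loadings)
  expect_equal(recon, z, tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("equicorrelated blocks give the closed-form leading eigenvalue", {
  # 3 columns at rho = 0.46 plus 1 independent: eigenvalues of the block
  # correlation matrix are (1 + 2 rho), 1, (1 - rho), (1 - rho)
  rho <- 0.46
  cm <- diag(4)
  cm[1:3, 1:3] <- rho; diag(cm) <- 1
  ev <- eigen(cm, symmetric = TRUE, only.values = TRUE)$values
  expect_equal(ev, c(1 + 2 * rho, 1, 1 - rho, 1 - rho), tolerance = 1e-12)
  expect_equal((1 + 2 * rho) / 4, 0.48)
  set.seed(38)
  n <- 20000
  a <- rnorm(n); lam <- sqrt(rho)
  x <- cbind(lam * a + sqrt(1 - rho) * rnorm(n),
             lam * a + sqrt(1 - rho) * rnorm(n),
             lam * a + sqrt(1 - rho) * rnorm(n),
             rnorm(n))
  expect_equal(pca_indices(x)$explained_fraction[1], 0.48, tolerance = 0.01)
})

test_that("power sample sizes match the noncentral-t search at benchmark effects", {
  expect_equal(n_per_group_for_power(1.0), 17)
  expect_equal(n_per_group_for_power(0.67), 36)
  expect_equal(n_per_group_for_power(0.2), 394)
  # independent oracle: stats::power.t.test solves the same design
  for (d in c(0.3, 0.5, 0.8)) {
    oracle <- ceiling(stats::power.t.test(delta = d, sd = 1, power = 0.8,
                                          sig.level = 0.05)$n)
    expect_equal(n_per_group_for_power(d), oracle)
  }
  expect_error(n_per_group_for_power(0), class = "addix_domain_error")
})

test_that("required n is non-increasing in effect size and alpha", {
  ds <- c(0.2, 0.4, 0.6, 0.9, 1.4)
  ns <- vapply(ds, n_per_group_for_power, numeric(1))
  expect_true(all(diff(ns) < 0))
  alphas <- c(0.01, 0.05, 0.1)
  na <- vapply(alphas, function(a) n_per_group_for_power(0.5, alpha = a),
               numeric(1))
  expect_true(all(diff(na) <= 0))
})

test_that("the cohort battery mirrors the designed population structure", {
  co <- default_cohort()
  s <- behavior_summaries(co)
  idx <- build_indices(s)
  batt <- stats_battery(s, idx)
  tests <- batt$tests
  get <- function(nm) tests[tests$statistic == nm, ]

  # single-cohort estimate: configured d = 0.67 with sampling se ~ 0.09
  expect_gt(get("sex_d_compulsivity")$estimate, 0.37)
  expect_lt(get("sex_d_compulsivity")$estimate, 0.97)
  expect_equal(get("withdrawal_irritability_d_vs_naive")$estimate, 0.89,
               tolerance = 0.35)
  expect_equal(get("preshock_shock_r")$estimate, 0.58, tolerance = 0.1)
  expect_lt(abs(get("sex_d_irritability")$estimate), 0.2)
  expect_gt(get("preshock_shock_paired_t")$estimate, 0)  # suppression
  expect_true(all(tests$ci_low <= tests$estimate &
                    tests$estimate <= tests$ci_high, na.rm = TRUE))

  # PC1 aligns the three addiction indices with irritability near-orthogonal
  l1 <- batt$pca$loadings[, 1]
  addiction <- l1[c("escalation_z", "motivation_z", "compulsivity_z")]
  expect_true(all(sign(addiction) == sign(addiction[1])))
  expect_true(all(abs(addiction) > 0.3))
  expect_lt(abs(l1[["irritability_z"]]), 0.25)
  # power rows exist for the positive significant sex effects
  expect_true(any(grepl("n_per_group_80pct_power_", tests$statistic)))
})
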