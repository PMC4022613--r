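# stats: group comparisons, regressions, trend tests, ICC

test_that("pooled t test matches base R and handles degenerate input", {
  set.seed(1)
  for (i in 1:25) {
    x <- rnorm(sample(5:40, 1)); y <- rnorm(sample(5:40, 1), mean = 0.5)
    got <- two_sample_t(x, y)
    ref <- t.test(y, x, var.equal = TRUE)
    expect_equal(got$statistic, unname(ref$statistic))
    expect_equal(got$p_value, ref$p.value)
  }
  same <- c(1, 2, 3)
  r <- two_sample_t(same, same)
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  r2 <- two_sample_t(rnorm(20, 0, 0.01), rnorm(20, 100, 0.01))
  expect_lt(r2$p_value, 1e-3)
  expect_error(two_sample_t(1, c(1, 2)), "n >= 2")
  expect_error(two_sample_t(c(1, 1), c(1, 1)), "pooled variance")
})

test_that("chi-square: hand values, invariance, base-R agreement", {
  r <- chi_square_test(matrix(c(10, 0, 0, 10), 2))
  expect_equal(r$statistic, 20)
  prop <- matrix(c(20, 10, 40, 20), 2)   # proportional rows
  expect_equal(chi_square_test(prop)$statistic, 0)
  expect_equal(chi_square_test(prop)$p_value, 1)
  set.seed(2)
  tab <- matrix(rpois(4, 30), 2)
  a <- chi_square_test(tab)
  expect_equal(a$statistic, chi_square_test(tab[2:1, ])$statistic)
  expect_equal(a$statistic, chi_square_test(tab[, 2:1])$statistic)
  ref <- suppressWarnings(chisq.test(tab, correct = FALSE))
  expect_equal(a$statistic, unname(ref$statistic))
  expect_equal(a$p_value, ref$p.value)
})

test_that("standardized OLS: coefficient scale, guards, affine invariance", {
  set.seed(3)
  x <- rnorm(80, 10, 4)
  y <- 2 * (x - mean(x)) / sd(x) + rnorm(80, sd = 0.5)
  fit <- ols_standardized(y, x)
  expect_lt(abs(fit$coefficient - 2), 3 * fit$se)
  # affine rescaling of the raw predictor is absorbed by standardization
  fit2 <- ols_standardized(y, 100 - 7 * x)
  expect_equal(abs(fit2$coefficient), abs(fit$coefficient))
  expect_equal(fit2$p_value, fit$p_value)
  # perfect fit -> degenerate
  z <- (x - mean(x)) / sd(x)
  expect_error(ols_standardized(2 * z, x), "degenerate|collinear")
  expect_error(ols_standardized(y, rep(1, 80)), "zero predictor variance")
  # covariates shift the estimate but keep the per-SD scale
  cov <- data.frame(age = rnorm(80, 50, 8),
                    sex = sample(c("F", "M"), 80, TRUE))
  fit3 <- ols_standardized(y, x, covariates = cov)
  expect_equal(fit3$covariates, c("age", "sex"))
  expect_lt(abs(fit3$coefficient - 2), 4 * fit3$se)
  # logistic route reports a finite coefficient on a binary outcome
  yb <- as.integer(y > median(y))
  fl <- ols_standardized(yb, x, logistic = TRUE)
  expect_true(is.finite(fl$coefficient) && fl$model == "logistic")
})

test_that("slope recovery across replicates (simulation oracle)", {
  set.seed(4)
  ests <- replicate(300, {
    x <- rnorm(60)
    y <- 1.5 * (x - mean(x)) / sd(x) + rnorm(60)
    ols_standardized(y, x)$coefficient
  })
  expect_lt(abs(mean(ests) - 1.5), 3 * sd(ests) / sqrt(300))
})

test_that("tertile assignment: balanced case, ties, degenerate input", {
  g <- tertile_assign(1:9)
  expect_equal(as.vector(table(g)), c(3L, 3L, 3L))
  expect_equal(g[1:3], rep(1L, 3))
  expect_error(tertile_assign(rep(5, 10)), "degenerate tertiles")
  expect_error(tertile_assign(c(1, 2)), "n >= 3")
  set.seed(5)
  for (i in 1:50) {
    v <- sample(0:20, 60, replace = TRUE)
    tt <- tertile_assign(v)
    # ties at a cut go to the lower tertile: group sizes differ from n/3 by
    # at most the number of observations tied with a boundary value
    q1 <- oracle_nearest_rank(v, 100 / 3); q2 <- oracle_nearest_rank(v, 200 / 3)
    slack <- sum(v == q1) + sum(v == q2)
    expect_true(all(abs(table(factor(tt, 1:3)) - 20) <= slack))
    expect_true(all(v[tt == 1] <= q1) && all(v[tt == 3] > q2))
  }
})

test_that("Cuzick trend: exact permutation moments and perfect trend", {
  # exhaustive check of E[T], Var[T] on a small tied dataset
  vals <- c(3, 1, 4, 1, 5, 9, 2, 6, 5)
  sizes <- c(3L, 3L, 3L)
  got <- cuzick_trend(vals, rep(1:3, each = 3))
  perms <- all_group_permutations(sizes)
  R <- rank(vals)
  Ts <- vapply(perms, function(lab) sum(lab * R), numeric(1))
  expect_equal(got$expected, mean(Ts))
  # the analytic permutation variance is exact: group assignments are
  # exchangeable, so the population variance over all relabelings matches
  expect_equal(got$variance, mean((Ts - mean(Ts))^2), tolerance = 1e-12)
  z_perm <- (got$T - mean(Ts)) / sqrt(mean((Ts - mean(Ts))^2))
  expect_lt(abs(got$statistic - z_perm), 0.02)
  # perfect monotone trend
  up <- cuzick_trend(c(1:10, 11:20, 21:30), rep(1:3, each = 10))
  expect_gt(up$statistic, 0)
  expect_lt(up$p_value, 0.05)
  down <- cuzick_trend(c(21:30, 11:20, 1:10), rep(1:3, each = 10))
  expect_equal(down$statistic, -up$statistic)
  expect_error(cuzick_trend(rep(1, 6), rep(1:2, each = 3)), "tied")
  expect_error(cuzick_trend(1:6, rep(1, 6)), ">= 2 ordered groups")
})

test_that("Kruskal-Wallis: hand-rank oracle, ties, permutation mean", {
  sep <- kruskal_wallis(list(1:3, 4:7, 8:10))
  # hand rank arithmetic: H = 12/(N(N+1)) * sum n_g rbar_g^2 - 3(N+1)
  expect_equal(sep$statistic, 12 / 110 * (3 * 2^2 + 4 * 5.5^2 + 3 * 9^2) - 33)
  expect_equal(sep$statistic, 8.01818181818, tolerance = 1e-9)
  ident <- kruskal_wallis(list(c(2, 2, 2), c(2, 2, 2)))
  expect_equal(ident$statistic, 0)
  # tie-corrected H agrees with base R on tied data
  set.seed(6)
  gs <- list(sample(1:5, 8, TRUE), sample(2:6, 7, TRUE),
             sample(3:7, 6, TRUE))
  expect_equal(kruskal_wallis(gs)$statistic,
               unname(kruskal.test(gs)$statistic))
  expect_equal(kruskal_wallis(gs)$p_value, kruskal.test(gs)$p.value)
  # exhaustive permutation: mean of H over all relabelings is k-1 (no ties)
  vals <- c(0.3, 1.2, 2.2, 3.1, 4.9, 5.5, 6.1, 7.7)
  sizes <- c(3L, 3L, 2L)
  perms <- all_group_permutations(sizes)
  Hs <- vapply(perms, function(lab)
    kruskal_wallis(split(vals, lab))$statistic, numeric(1))
  expect_equal(mean(Hs), 2, tolerance = 1e-10)
  expect_error(kruskal_wallis(list(1:2, 2:3)), ">= 5")
})

test_that("Pearson correlation including the fibrosis-score example", {
  expect_equal(pearson_r(1:5, 1:5), 1)
  expect_equal(pearson_r(1:5, -(1:5)), -1)
  # fibrosis scores 3.2/8.1/23.3 vs group index; closed form frozen
  expect_equal(pearson_r(1:3, c(3.2, 8.1, 23.3)), 0.9589130078,
               tolerance = 1e-9)
  expect_error(pearson_r(1:2, 1:2), "n >= 3")
})

test_that("ICC(2,1): identity, null, and variance-components recovery", {
  set.seed(7)
  subj <- rnorm(30, 10, 2)
  exact <- icc_reproducibility(cbind(subj, subj))
  expect_equal(exact$icc, 1)
  noise <- matrix(rnorm(60), 30, 2)
  expect_lt(abs(icc_reproducibility(noise)$icc), 0.35)
  # known variance components: ICC ~= sb^2/(sb^2+se^2)
  sb <- 2; se_ <- 1
  target <- sb^2 / (sb^2 + se_^2)
  reps <- replicate(200, {
    s <- rnorm(40, 0, sb)
    icc_reproducibility(cbind(s + rnorm(40, 0, se_),
                              s + rnorm(40, 0, se_)))$icc
  })
  expect_lt(abs(mean(reps) - target), 3 * sd(reps) / sqrt(200))
  m <- cbind(subj, subj + rnorm(30))
  m[2, 2] <- NA
  expect_error(icc_reproducibility(m), "missing cells")
  expect_error(icc_reproducibility(cbind(1:4, 1:4)), ">= 5 subjects")
})

test_that("clinical analysis grid has the expected shape and consistency", {
  tab <- attach_derived(simulate_cohort(cohort_params_clinical(
    n_control = 300L, n_hypertensive = 300L, seed = 11)))
  b <- run_clinical_analysis(tab)
  expect_named(b, c("group_comparison", "status_regression",
                    "bp_regression", "tertile_trend"))
  expect_true("sex" %in% b$group_comparison$variable)
  expect_equal(nrow(b$status_regression), 9 * 2)
  expect_equal(nrow(b$bp_regression), 9 * 2 * 3)
  expect_equal(nrow(b$tertile_trend), 9 * 3)
  # at clinical parameters and large n the SIC and MSI separate groups
  sic_adj <- subset(b$status_regression, variable == "sic" &
                      model == "adjusted")
  expect_lt(sic_adj$p, 0.05)
  # no covariates equals the unadjusted panel (and emits only that panel)
  b0 <- run_clinical_analysis(tab, covariates = character(0))
  expect_true(all(b0$status_regression$model == "unadjusted"))
  un <- subset(b$status_regression, model == "unadjusted")
  expect_equal(un$coefficient, b0$status_regression$coefficient)
  expect_error(run_clinical_analysis(tab[setdiff(names(tab), "msi")]),
               "missing column.*msi")
  # bundle writer produces the tidy CSVs
  dir <- tempfile()
  paths <- write_analysis_bundle(b, dir)
  expect_true(file.exists(file.path(dir, "tertile_trend.csv")))
  back <- read.csv(file.path(dir, "status_regression.csv"))
  expect_equal(nrow(back), nrow(b$status_regression))
})

test_that("null cohort shows no systematic significance", {
  # same distribution in both groups: fraction of p<0.05 across the
  # regression grid stays near alpha
  g <- list(n = 100L, women_frac = 0.5,
            means = c(age = 52, sbp = 121, dbp = 72, ivs = 0.9, pw = 0.9,
                      lvdd = 4.0, fs = 0.28, e_prime = 13.2, e_vel = 82,
                      a_vel = 68, sic = 0.23),
            sds = c(age = 9, sbp = 9, dbp = 9, ivs = 0.14, pw = 0.14,
                    lvdd = 0.5, fs = 0.08, e_prime = 3.1, e_vel = 16,
                    a_vel = 14, sic = 0.11))
  ps <- unlist(lapply(1:20, function(i) {
    params <- cohort_params(list(control = g, hypertensive = g), seed = i)
    tab <- attach_derived(simulate_cohort(params))
    run_clinical_analysis(tab)$status_regression$p
  }))
  expect_lt(mean(ps < 0.05), 0.12)
})
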