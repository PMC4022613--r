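# Statistical evaluation pipeline: pooled two-sample t, Pearson chi-square,
# standardized OLS with covariate adjustment, nearest-rank tertiles, the
# Cuzick rank test for trend across ordered groups, tie-corrected
# Kruskal-Wallis, Pearson correlation, and ICC(2,1) reader reproducibility.
# All p values are two-sided; no multiplicity adjustment is applied.

stat_result <- function(test_name, statistic, p_value, estimate = NA_real_,
                        se = NA_real_, n = NA_integer_, df = NA_real_,
                        extra = list()) {
  structure(c(list(test_name = test_name, statistic = statistic,
                   p_value = p_value, estimate = estimate, se = se,
                   n = n, df = df), extra),
            class = "stat_test_result")
}

#' @export
print.stat_test_result <- function(x, ...) {
  cat(sprintf("<%s: statistic %.4g, p %.4g (n = %s)>\n",
              x$test_name, x$statistic, x$p_value, x$n))
  invisible(x)
}

#' Pooled-variance two-sample Student t test
#'
#' Classic Student t with the pooled variance estimate (not Welch),
#' two-sided p on `n1 + n2 - 2` degrees of freedom.
#'
#' @param x,y numeric samples, each of length `>= 2`.
#' @return A `stat_test_result` with `estimate` = mean(y) - mean(x) and its
#'   pooled standard error.
#' @export
two_sample_t <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2L || n2 < 2L) stop("each group needs n >= 2")
  sp2 <- ((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) / (n1 + n2 - 2)
  if (sp2 <= 0) stop("zero pooled variance")
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  est <- mean(y) - mean(x)
  tt <- est / se
  df <- n1 + n2 - 2
  stat_result("two_sample_t_pooled", tt,
              2 * stats::pt(-abs(tt), df), estimate = est, se = se,
              n = n1 + n2, df = df)
}

#' Pearson chi-square test of independence
#'
#' No continuity correction, df = (rows-1)(cols-1).
#'
#' @param tab contingency matrix of nonnegative counts (2x2 in the standard
#'   use).
#' @return A `stat_test_result`.
#' @export
chi_square_test <- function(tab) {
  tab <- as.matrix(tab)
  if (any(tab < 0) || sum(tab) <= 0) stop("counts must be >= 0, total > 0")
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected == 0)) stop("degenerate margin (zero expected count)")
  stat <- sum((tab - expected)^2 / expected)
  df <- (nrow(tab) - 1) * (ncol(tab) - 1)
  stat_result("chi_square", stat, stats::pchisq(stat, df, lower.tail = FALSE),
              n = sum(tab), df = df)
}

#' Standardized regression of an outcome on a predictor
#'
#' The predictor is standardized to mean 0, SD 1 (sample SD, `n - 1`)
#' before fitting, so the reported coefficient is the change in outcome per
#' 1-SD change in the predictor. Covariates enter unstandardized. Binary
#' outcomes are fitted as a linear probability model by default; set
#' `logistic = TRUE` for logistic regression instead.
#'
#' @param outcome numeric (or 0/1) response vector.
#' @param predictor numeric predictor, nonzero variance.
#' @param covariates optional data.frame of adjustment covariates (numeric
#'   or factor/character).
#' @param logistic fit a logistic model for a binary outcome.
#' @return A `regression_result` list: `coefficient` (per 1-SD), `se`,
#'   `p_value`, `covariates`, `n`, `model`.
#' @export
ols_standardized <- function(outcome, predictor, covariates = NULL,
                             logistic = FALSE) {
  n <- length(outcome)
  if (length(predictor) != n) stop("outcome/predictor length mismatch")
  ncov <- if (is.null(covariates)) 0L else ncol(covariates)
  if (n <= ncov + 2L) stop("insufficient n for the design")
  sx <- stats::sd(predictor)
  if (!is.finite(sx) || sx == 0) stop("zero predictor variance")
  z <- (predictor - mean(predictor)) / sx
  dat <- data.frame(.y = outcome, .z = z)
  rhs <- ".z"
  if (ncov > 0L) {
    covariates <- as.data.frame(covariates)
    for (nm in names(covariates)) {
      cv <- covariates[[nm]]
      dat[[nm]] <- if (is.character(cv)) factor(cv) else cv
    }
    rhs <- paste(c(".z", names(covariates)), collapse = " + ")
  }
  fml <- stats::as.formula(paste(".y ~", rhs))
  fit <- if (logistic) stats::glm(fml, data = dat, family = stats::binomial())
         else stats::lm(fml, data = dat)
  smry <- suppressWarnings(summary(fit))  # perfect fits warn before we error
  if (!logistic) {
    sig2 <- smry$sigma^2
    if (!is.finite(sig2) || sig2 <= 1e-10 * max(stats::var(outcome), 1e-300))
      stop("degenerate fit: zero residual variance")
  }
  sm <- smry$coefficients
  if (!".z" %in% rownames(sm)) stop("collinear design: predictor dropped")
  coef_z <- sm[".z", 1]; se_z <- sm[".z", 2]
  if (!is.finite(se_z) || se_z <= 0 || is.nan(sm[".z", 4]))
    stop("degenerate fit: zero residual variance")
  structure(list(coefficient = coef_z, se = se_z, p_value = sm[".z", 4],
                 covariates = if (ncov > 0L) names(covariates) else character(0),
                 n = n, model = if (logistic) "logistic" else "ols"),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  adj <- if (length(x$covariates))
    paste0(" | ", paste(x$covariates, collapse = ", ")) else ""
  cat(sprintf("<%s: %.4g (SE %.4g) per 1-SD%s, p %.4g, n %d>\n",
              x$model, x$coefficient, x$se, adj, x$p_value, x$n))
  invisible(x)
}

#' Assign tertiles by nearest-rank cut points
#'
#' Cuts at the 33.3rd and 66.7th nearest-rank percentiles; ties at a cut
#' point go to the lower tertile. Groups are ordinal 1, 2, 3.
#'
#' @param values numeric vector, `n >= 3`, not all equal.
#' @return Integer vector of tertile indices.
#' @export
tertile_assign <- function(values) {
  if (length(values) < 3L) stop("need n >= 3 for tertiles")
  q1 <- percentile_nearest_rank(values, 100 / 3)
  q2 <- percentile_nearest_rank(values, 200 / 3)
  if (q1 == q2 && q1 == max(values)) stop("degenerate tertiles: values tied")
  g <- 1L + (values > q1) + (values > q2)
  if (length(unique(g)) < 2L) stop("degenerate tertiles: values tied")
  g
}

#' Cuzick nonparametric test for trend across ordered groups
#'
#' Rank test for monotone trend: with pooled midranks `R_i` and group
#' scores `l_g` (default 1, 2, ..., k), the statistic is
#' `T = sum_i l_{g(i)} R_i`; its exact permutation mean and variance
#' (tie-corrected through the midranks) give
#' `z = (T - E[T]) / sqrt(Var[T])` and a two-sided normal p value.
#'
#' @param values numeric observations.
#' @param groups ordinal group labels (integer, ordered factor, or anything
#'   coercible); trend is tested along the sorted unique labels.
#' @param scores optional numeric group scores; default equally spaced
#'   1..k.
#' @return A `stat_test_result` with `statistic` = z and extras `T`,
#'   `expected`, `variance`.
#' @export
cuzick_trend <- function(values, groups, scores = NULL) {
  g <- as.integer(factor(groups, levels = sort(unique(groups))))
  k <- max(g)
  if (k < 2L) stop("need >= 2 ordered groups")
  if (any(tabulate(g, k) == 0L)) stop("a group is empty")
  n <- length(values)
  if (length(unique(values)) == 1L) stop("all values tied")
  if (is.null(scores)) scores <- seq_len(k)
  l <- scores[g]
  R <- rank(values)                       # midranks
  T_obs <- sum(l * R)
  lbar <- mean(l); Rbar <- mean(R)
  ET <- n * lbar * Rbar
  VT <- sum((l - lbar)^2) * sum((R - Rbar)^2) / (n - 1)
  if (VT <= 0) stop("degenerate trend statistic")
  z <- (T_obs - ET) / sqrt(VT)
  stat_result("cuzick_trend", z, 2 * stats::pnorm(-abs(z)), n = n,
              extra = list(T = T_obs, expected = ET, variance = VT,
                           scores = scores))
}

#' Kruskal-Wallis rank test (tie-corrected)
#'
#' `H = (N - 1) * sum_g n_g (rbar_g - rbar)^2 / sum_i (R_i - rbar)^2`
#' with midranks, which reduces to the classic `12/(N(N+1)) ...` form in the
#' absence of ties; p from chi-square with `k - 1` df.
#'
#' @param groups a list of numeric vectors (one per group).
#' @return A `stat_test_result`.
#' @export
kruskal_wallis <- function(groups) {
  k <- length(groups)
  if (k < 2L) stop("need >= 2 groups")
  ns <- lengths(groups)
  if (any(ns < 1L)) stop("a group is empty")
  N <- sum(ns)
  if (N < 5L) stop("total n must be >= 5")
  x <- unlist(groups)
  g <- rep(seq_len(k), ns)
  R <- rank(x)
  rbar <- mean(R)
  ss_between <- sum(tapply(R, g, function(r) length(r) * (mean(r) - rbar)^2))
  ss_total <- sum((R - rbar)^2)
  if (ss_total == 0) {
    H <- 0
  } else {
    H <- (N - 1) * ss_between / ss_total
  }
  stat_result("kruskal_wallis", H,
              stats::pchisq(H, k - 1, lower.tail = FALSE), n = N, df = k - 1)
}

#' Pearson correlation
#'
#' @param x,y numeric vectors, `n >= 3`.
#' @return The sample correlation coefficient.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch")
  if (length(x) < 3L) stop("need n >= 3")
  stats::cor(x, y)
}

#' ICC(2,1): two-way random effects, absolute agreement, single rating
#'
#' Computed from the two-way ANOVA mean squares:
#' `(MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)` with subjects as
#' rows and readers/readings as columns.
#'
#' @param ratings numeric matrix, subjects x readings, `>= 5` subjects,
#'   `>= 2` readings, no missing cells.
#' @return List with `icc`, `ms` (the three mean squares), `n`, `k`.
#' @export
icc_reproducibility <- function(ratings) {
  ratings <- as.matrix(ratings)
  n <- nrow(ratings); k <- ncol(ratings)
  if (n < 5L) stop("need >= 5 subjects")
  if (k < 2L) stop("need >= 2 readings per subject")
  if (anyNA(ratings)) stop("missing cells are not allowed")
  grand <- mean(ratings)
  rowm <- rowMeans(ratings); colm <- colMeans(ratings)
  ssr <- k * sum((rowm - grand)^2)
  ssc <- n * sum((colm - grand)^2)
  sst <- sum((ratings - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1); msc <- ssc / (k - 1); mse <- sse / ((n - 1) * (k - 1))
  if (msr <= 0) stop("zero between-subject variance")
  icc <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  list(icc = icc, ms = c(MSR = msr, MSC = msc, MSE = mse), n = n, k = k)
}

#' Run the full clinical analysis grid on a cohort table
#'
#' Reproduces the evaluation pipeline on a (derived-column) cohort table:
#' per-variable two-group comparisons (t test for continuous variables,
#' chi-square for sex), unadjusted and covariate-adjusted standardized
#' regressions of group status on each echocardiographic measure, the same
#' regressions against each blood-pressure index, and nonparametric trend
#' tests across tertiles of each blood-pressure index.
#'
#' @param cohort data.frame with columns `group` (two levels), `age`,
#'   `sex`, `sbp`, `dbp`, `map`, and the echo measures in `echo_vars`.
#' @param covariates character vector of adjustment covariates (default
#'   `c("age", "sex")`).
#' @param echo_vars echocardiographic measures to analyze.
#' @param bp_vars blood-pressure indices.
#' @param logistic use logistic rather than linear-probability models for
#'   group status.
#' @return A list of tidy data.frames: `group_comparison`,
#'   `status_regression`, `bp_regression`, `tertile_trend`.
#' @export
run_clinical_analysis <- function(cohort,
                                  covariates = c("age", "sex"),
                                  echo_vars = c("lvwt", "lvdd", "lv_mass",
                                                "rwt", "e_prime",
                                                "e_a_ratio",
                                                "e_eprime_ratio", "sic",
                                                "msi"),
                                  bp_vars = c("sbp", "dbp", "map"),
                                  logistic = FALSE) {
  need <- unique(c("group", covariates, bp_vars, echo_vars))
  missing_cols <- setdiff(need, names(cohort))
  if (length(missing_cols))
    stop("missing column(s): ", toString(missing_cols))
  glev <- sort(unique(cohort$group))
  if (length(glev) != 2L) stop("group must have exactly two levels")
  status <- as.integer(cohort$group == glev[2])

  cont_vars <- unique(c(bp_vars, echo_vars, intersect("age", names(cohort))))
  group_comparison <- do.call(rbind, lapply(cont_vars, function(v) {
    r <- two_sample_t(cohort[[v]][status == 0L], cohort[[v]][status == 1L])
    data.frame(variable = v, test = r$test_name, statistic = r$statistic,
               estimate = r$estimate, se = r$se, p = r$p_value, n = r$n)
  }))
  if ("sex" %in% names(cohort)) {
    tab <- table(cohort$sex, cohort$group)
    r <- chi_square_test(tab)
    group_comparison <- rbind(group_comparison,
      data.frame(variable = "sex", test = r$test_name,
                 statistic = r$statistic, estimate = NA_real_,
                 se = NA_real_, p = r$p_value, n = r$n))
  }

  covariate_sets <- list(unadjusted = character(0))
  if (length(covariates)) covariate_sets$adjusted <- covariates
  regress_grid <- function(outcome, outcome_name, use_logistic) {
    do.call(rbind, lapply(echo_vars, function(v) {
      rows <- lapply(covariate_sets, function(cv) {
        fit <- ols_standardized(outcome, cohort[[v]],
                                covariates = if (length(cv))
                                  cohort[cv] else NULL,
                                logistic = use_logistic)
        data.frame(outcome = outcome_name, variable = v,
                   model = if (length(cv)) "adjusted" else "unadjusted",
                   coefficient = fit$coefficient, se = fit$se,
                   p = fit$p_value, n = fit$n)
      })
      do.call(rbind, rows)
    }))
  }
  status_regression <- regress_grid(status, "status", logistic)
  bp_regression <- do.call(rbind, lapply(bp_vars, function(bp)
    regress_grid(cohort[[bp]], bp, FALSE)))

  tertile_trend <- do.call(rbind, lapply(bp_vars, function(bp) {
    tert <- tertile_assign(cohort[[bp]])
    do.call(rbind, lapply(echo_vars, function(v) {
      r <- cuzick_trend(cohort[[v]], tert)
      data.frame(bp_measure = bp, variable = v, z = r$statistic,
                 p = r$p_value, n = r$n)
    }))
  }))

  list(group_comparison = group_comparison,
       status_regression = status_regression,
       bp_regression = bp_regression,
       tertile_trend = tertile_trend)
}

#' Write an analysis bundle to CSV + JSON
#'
#' @param bundle result of [run_clinical_analysis()].
#' @param dir output directory (created if absent).
#' @return Character vector of written paths, invisibly.
#' @export
write_analysis_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (nm in names(bundle)) {
    p <- file.path(dir, paste0(nm, ".csv"))
    utils::write.csv(bundle[[nm]], p, row.names = FALSE)
    paths <- c(paths, p)
  }
  jp <- file.path(dir, "analysis_bundle.json")
  jsonlite::write_json(bundle, jp, dataframe = "rows", digits = NA)
  invisible(c(paths, jp))
}
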